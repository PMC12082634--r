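options(scramblekit.quiet = TRUE)

# a tiny two-site synthetic membrane used across tests
small_system <- function(rates = list(POPC = c(Sec61 = 2, TRAP = 1)),
                         n_per_leaflet = c(POPC = 100),
                         n_frames = 500, seed = 7, ...) {
  generate_trajectory(synthetic_spec(
    n_per_leaflet = n_per_leaflet, rates = rates,
    sites = list(Sec61 = c(4.5, 7.5), TRAP = c(10.5, 7.5)),
    n_frames = n_frames, seed = seed, ...))
}

# hand-built 4-lipid single-frame GRO fixture (POPC head/tail pairs)
write_fixture_gro <- function(path, drop_tail_of = NULL) {
  lines <- c("fixture t= 0.0", "    8")
  zs <- c(8, 5, 8, 5, 4, 7, 4, 7)
  k <- 0
  for (i in 1:4) {
    for (bead in c("PO4", "C4B")) {
      k <- k + 1
      if (!is.null(drop_tail_of) && i == drop_tail_of && bead == "C4B") {
        bead <- "C4A"  # wrong tail bead name
      }
      lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                i, "POPC", bead, k,
                                1.0 * i, 2.0, zs[k]))
    }
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 15, 15, 12))
  writeLines(lines, path)
  path
}

popc_selmap <- function() {
  bead_selection_map(lipids = list(POPC = list(head = "PO4", tail = "C4B")))
}
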