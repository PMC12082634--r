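# independent queue-based flood fill over 26-connected voxels; used as
# the reference for pathway_continuity
flood_fill_bridges <- function(mask, iz1, iz2) {
  dims <- dim(mask)
  visited <- array(FALSE, dims)
  starts <- which(mask[, , iz1], arr.ind = TRUE)
  if (nrow(starts) == 0) return(FALSE)
  queue <- cbind(starts, iz1)
  visited[queue] <- TRUE
  while (nrow(queue) > 0) {
    v <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    if (v[3] == iz2) return(TRUE)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > dims)) next
      if (mask[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]]) {
        visited[w[1], w[2], w[3]] <- TRUE
        queue <- rbind(queue, w)
      }
    }
  }
  any(visited[, , iz2])
}
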