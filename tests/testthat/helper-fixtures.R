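# shared fixtures and independent oracles (all built in code at test time)

maxabs <- function(a, b) {
  av <- if (inherits(a, "video_tensor")) a$values else a
  bv <- if (inherits(b, "video_tensor")) b$values else b
  max(abs(av - bv))
}

rel_err <- function(a, b) {
  m <- max(abs(a), abs(b))
  if (m == 0) 0 else max(abs(a - b)) / m
}

small_noise <- function(shape = c(6L, 6L), frames = 20L, seed = 1, level = 1) {
  gaussian_noise(shape = shape, frames = frames, mean = 0, level = level, seed = seed)
}

# independent brute-force conv3d oracle: triple-nested loops, no shared code
# with the package's gemm implementation
brute_conv3d <- function(xv, w) {
  d <- dim(xv); dw <- dim(w)
  cx <- (dw[4L] + 1L) %/% 2L; cy <- (dw[5L] + 1L) %/% 2L
  out <- array(0, c(d[1L], dw[1L], d[3L], d[4L], d[5L]))
  for (b in seq_len(d[1L])) for (co in seq_len(dw[1L])) {
    for (k in seq_len(d[3L])) for (x in seq_len(d[4L])) for (y in seq_len(d[5L])) {
      acc <- 0
      for (ci in seq_len(dw[2L])) for (j in seq_len(dw[3L])) {
        kk <- k + j - dw[3L]
        if (kk < 1L || kk > d[3L]) next
        for (u in seq_len(dw[4L])) {
          xx <- x + u - cx
          if (xx < 1L || xx > d[4L]) next
          for (v in seq_len(dw[5L])) {
            yy <- y + v - cy
            if (yy < 1L || yy > d[5L]) next
            acc <- acc + w[co, ci, j, u, v] * xv[b, ci, kk, xx, yy]
          }
        }
      }
      out[b, co, k, x, y] <- acc
    }
  }
  out
}
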