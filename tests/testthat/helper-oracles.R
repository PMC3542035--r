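# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# per-pixel sorted-neighborhood 3x3 median with edge replication
oracle_median3 <- function(img) {
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0L, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    vals <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1L), M)
      jj <- min(max(j + dj, 1L), N)
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- sort(vals)[5L]
  }
  out
}

# plain-recursive quadtree on an already power-of-two square image;
# returns data.frame(top, left, size), 1-based (preallocated accumulators
# keep the brute force affordable on fully split images)
oracle_quadtree <- function(img, thresh) {
  stopifnot(nrow(img) == ncol(img))
  p <- nrow(img)
  tops <- integer(p * p); lefts <- integer(p * p); sizes <- integer(p * p)
  n <- 0L
  rec <- function(top, left, size) {
    block <- img[top:(top + size - 1L), left:(left + size - 1L)]
    if (size > 1L && (max(block) - min(block)) > thresh) {
      h <- size %/% 2L
      rec(top, left, h); rec(top, left + h, h)
      rec(top + h, left, h); rec(top + h, left + h, h)
    } else {
      n <<- n + 1L
      tops[n] <<- top; lefts[n] <<- left; sizes[n] <<- size
    }
  }
  rec(1L, 1L, p)
  data.frame(top = tops[seq_len(n)], left = lefts[seq_len(n)],
             size = sizes[seq_len(n)])
}

# edge replication to power-of-two square, independent of the package helper
oracle_pad <- function(img) {
  p <- 1L
  while (p < max(dim(img))) p <- p * 2L
  img[pmin(seq_len(p), nrow(img)), pmin(seq_len(p), ncol(img)), drop = FALSE]
}

# two-pass population sigma of normalized gray levels
oracle_w1 <- function(ls) {
  x <- as.vector(ls) / 255
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / length(x)
  1 - 1 / (1 + v)
}

# explicit scan over gray levels for the noise-thresholded minimum
oracle_w2 <- function(ls, threshold = 0.2) {
  counts <- sapply(0:255, function(i) sum(ls == i))
  modal <- max(counts)
  for (i in 0:255) if (counts[i + 1L] > threshold * modal) return(i)
  stop("unreachable: the modal bin always survives")
}

rand_image <- function(M, N = M, levels = 0:255) {
  matrix(sample(levels, M * N, replace = TRUE), M, N)
}

# smoother random image exercising the no-split quadtree path
rand_smooth_image <- function(M, N = M, base = 100, spread = 10) {
  matrix(pmin(pmax(base + sample(-spread:spread, M * N, replace = TRUE), 0),
              255), M, N)
}

# random feature frame with two Gaussian classes for classifier tests
rand_feature_frame <- function(n_per_class, mu_healthy, mu_patient,
                               sigma = diag(3)) {
  ch <- chol(sigma)
  draw <- function(n, mu) {
    X <- matrix(rnorm(n * 3), n, 3) %*% ch
    sweep(X, 2L, mu, `+`)
  }
  X <- rbind(draw(n_per_class, mu_healthy), draw(n_per_class, mu_patient))
  colnames(X) <- c("w1", "w2", "w3")
  data.frame(subject_id = sprintf("S%05d", seq_len(2 * n_per_class)),
             view = "LO",
             label = rep(c("healthy", "patient"), each = n_per_class), X)
}

# the constructed 16x16 quadtree fixture: NW/NE constant quadrants, SW/SE
# 1-px checkerboards of {0, 255}; exactly two final 8x8 blocks
quadtree_fixture16 <- function() {
  img <- matrix(0L, 16L, 16L)
  img[1:8, 9:16] <- 100L
  checker <- outer(1:8, 1:8, function(i, j) ((i + j) %% 2L) * 255L)
  img[9:16, 1:8] <- checker
  img[9:16, 9:16] <- checker
  img
}

# shared default synthetic cohort (60/60, fixed seed), built once per run
.fixture_env <- new.env(parent = emptyenv())
default_cohort_60 <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(cohort_config(60, 60, seed = 1234))
    .fixture_env$features <- extract_cohort_features(.fixture_env$cohort)
  }
  list(cohort = .fixture_env$cohort, features = .fixture_env$features)
}
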