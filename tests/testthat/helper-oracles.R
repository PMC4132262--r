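# independent oracles and shared fixtures for the test suite

# cache expensive fixtures across test files
.fixture_env <- new.env()

toy_fab_cached <- function(seed = 1) {
  key <- paste0("fab", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_toy_fab(seed)
  .fixture_env[[key]]
}

toy_fab_energy_cached <- function(seed = 1) {
  key <- paste0("fabE", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- fold_energy(toy_fab_cached(seed))
  .fixture_env[[key]]
}

# --- independent affine-gap global alignment (Gotoh DP), used as the oracle
# for pairwise_identity.  Returns the optimal score and the identity of a
# high-road optimal alignment recovered by traceback.
oracle_align <- function(a, b, open = 10, extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 2) * extend
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 2) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- as.numeric(x[i - 1] == y[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open, Iy[i, j - 1] - extend)
    }
  }
  best <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback (M preferred, then Ix, then Iy) counting matches and columns
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  nmatch <- 0; len <- 0
  while (i > 1 || j > 1) {
    len <- len + 1
    if (state == 1) {
      s <- as.numeric(x[i - 1] == y[j - 1])
      nmatch <- nmatch + s
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- M[i - 1, j] - open
      state <- if (Ix[i, j] == from_m) 1 else 2
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - open
      state <- if (Iy[i, j] == from_m) 1 else 3
      j <- j - 1
    }
  }
  list(score = best, identity = 100 * nmatch / len)
}

# --- brute-force T20: score query against every database entry with the
# package's pairwise_identity, sort, average the top k
oracle_t20 <- function(qstring, db, k = 20) {
  ids <- sort(vapply(db, function(s) pairwise_identity(qstring, s),
                     numeric(1)), decreasing = TRUE)
  mean(ids[seq_len(min(k, length(ids)))])
}

# --- brute-force epitope scan: enumerate every window and core offset
oracle_epitopes <- function(seq, m, thresholds) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  win_len <- min(15, n)
  out <- NULL
  for (st in seq_len(max(1, n - win_len + 1))) {
    best <- -Inf; best_core <- NA
    for (o in 0:(win_len - 9)) {
      core <- res[(st + o):(st + o + 8)]
      sc <- sum(m[cbind(1:9, match(core, colnames(m)))])
      if (sc > best) { best <- sc; best_core <- st + o }
    }
    if (best >= thresholds[2])
      out <- rbind(out, data.frame(start = st, core_start = best_core,
                                   score = best))
  }
  out
}

# random V-region of given length (uniform residues, single FR1 region)
random_vregion <- function(len, chain_kind = "heavy") {
  v_region(paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        len, replace = TRUE), collapse = ""),
           chain_kind)
}
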