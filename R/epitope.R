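# matrix-based MHC class II T-cell epitope scanning
#
# A transparent position-specific scoring matrix over 9-mer binding cores
# stands in for trained neural predictors: each 15-mer window is scored by
# its best 9-mer core, and windows above a moderate-affinity threshold are
# reported.  A bundled toy matrix exercises the machinery; real matrices can
# be supplied as CSV.

#' Read a 9 x 20 epitope scoring matrix from CSV
#'
#' Expected layout: one row per core position P1..P9, one column per
#' amino-acid letter (plus an optional leading position column).
#'
#' @param file CSV path.
#' @return numeric 9 x 20 matrix with amino-acid column names.
#' @export
read_epitope_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] %in% c("pos", "position", "P")) df <- df[, -1, drop = FALSE]
  m <- as.matrix(df)
  validate_epitope_matrix(m)
  m
}

validate_epitope_matrix <- function(m) {
  if (!is.numeric(m) || nrow(m) != 9 || ncol(m) != 20 ||
      !setequal(colnames(m), AA1))
    stopf("epitope matrix must be numeric 9 x 20 with the 20 amino-acid columns")
  if (!all(is.finite(m))) stopf("epitope matrix has non-finite entries")
  invisible(m)
}

#' The bundled toy epitope matrix
#' @return 9 x 20 matrix.
#' @export
toy_epitope_matrix <- function() read_epitope_matrix(abr_file("epitope", "toy_matrix.csv"))

score_core <- function(m, core) {
  j <- match(core, colnames(m))
  if (anyNA(j)) stopf("non-standard amino-acid letter in sequence")
  sum(m[cbind(seq_len(9), j)])
}

#' Scan a sequence for MHC class II epitopes
#'
#' Every 15-mer window is scored by the best of its seven 9-mer core offsets
#' (leftmost core wins ties); for sequences of length 9-14 the window is the
#' whole sequence.  Windows scoring at or above the moderate threshold are
#' returned as hits, sorted by position, and classed `high` or `moderate`
#' against the two thresholds.  Core intervals are 1-based, length 9,
#' inclusive start / exclusive end.
#'
#' @param seq amino-acid string or [v_region()].
#' @param matrix 9 x 20 scoring matrix (default: bundled toy matrix).
#' @param thresholds numeric `c(high, moderate)` with high >= moderate.
#' @return data frame of class `epitope_hits`: start, core_start, peptide,
#'   score, affinity_class.
#' @export
scan_epitopes <- function(seq, matrix = toy_epitope_matrix(),
                          thresholds = c(high = 6, moderate = 3)) {
  if (inherits(seq, "v_region")) seq <- as.character(seq)
  validate_epitope_matrix(matrix)
  if (length(thresholds) != 2 || thresholds[1] < thresholds[2])
    stopf("thresholds must be c(high, moderate) with high >= moderate")
  res <- strsplit(toupper(seq), "")[[1]]
  n <- length(res)
  if (n < 9) stopf("sequence shorter than a 9-mer core")
  win_len <- min(15L, n)
  starts <- seq_len(max(1L, n - win_len + 1L))
  out <- lapply(starts, function(st) {
    win <- res[st:(st + win_len - 1)]
    offs <- seq_len(win_len - 9 + 1)
    sc <- vapply(offs, function(o) score_core(matrix, win[o:(o + 8)]), numeric(1))
    best <- which.max(sc)  # leftmost tie
    data.frame(start = st, core_start = st + best - 1L,
               peptide = paste(win, collapse = ""), score = sc[best],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, out)
  hits <- hits[hits$score >= thresholds[2], , drop = FALSE]
  hits$affinity_class <- ifelse(hits$score >= thresholds[1], "high", "moderate")
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("epitope_hits", class(hits))
  hits
}

#' Mutations falling inside predicted epitope cores
#'
#' Pairs each mutation with every hit whose 9-mer core contains the mutated
#' position (core interval `[core_start, core_start + 9)`).
#'
#' @param hits result of [scan_epitopes()].
#' @param muts list of [point_mutation()] on the same coordinate system.
#' @return data frame: mutation, hit core_start, score, affinity_class.
#' @export
epitope_overlap <- function(hits, muts) {
  if (inherits(muts, "point_mutation")) muts <- list(muts)
  rows <- list()
  for (m in muts) {
    if (!nrow(hits)) break
    inside <- m$position >= hits$core_start & m$position < hits$core_start + 9
    if (any(inside)) {
      h <- hits[inside, , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        mutation = format(m), position = m$position,
        core_start = h$core_start, score = h$score,
        affinity_class = h$affinity_class, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mutation = character(), position = integer(),
                      core_start = integer(), score = numeric(),
                      affinity_class = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
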