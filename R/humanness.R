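# T20-style humanness scoring against a human V-sequence database

#' Percent identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match +1 / mismatch 0 and affine
#' gaps (open -10, extend -1), delegated to
#' [Biostrings::pairwiseAlignment()].  Identity is 100 * matches /
#' alignment length, where the denominator includes gap columns — indels are
#' penalized, as the humanness literature intends (configurable via
#' `denominator`).
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param denominator `"alignment"` (default; includes gap columns) or
#'   `"shorter"` (length of the shorter sequence).
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, gap_open = 10, gap_extend = 1,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stopf("empty sequence")
  sub <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = sub, type = "global",
    gapOpening = gap_open, gapExtension = gap_extend)
  nm <- Biostrings::nmatch(aln)
  len <- switch(denominator,
                alignment = nchar(as.character(Biostrings::alignedPattern(aln))),
                shorter = min(nchar(a), nchar(b)))
  100 * nm / len
}

# query string used for scoring: full V-region or framework-only
# (CDR positions spliced out)
humanness_query <- function(query, framework_only) {
  if (is.character(query)) {
    if (framework_only)
      stopf("framework-only scoring needs a v_region with a region map")
    return(query)
  }
  stopifnot(inherits(query, "v_region"))
  res <- query$residues
  if (framework_only) res <- res[startsWith(query$region_map, "FR")]
  paste(res, collapse = "")
}

#' T20 humanness score of a V-region
#'
#' Scores the query against every database sequence by global-alignment
#' percent identity and returns the mean of the top 20 identities (top
#' min(20, database size) for small databases).  With `framework_only`,
#' CDR positions are removed from the query before alignment, giving the
#' framework-only flavour of the score.  The retrieval step of the original
#' tool is replaced by an exhaustive scan, which yields the identical
#' top-20 set at desk scale.  Absolute scores are database-dependent.
#'
#' @param query a [v_region()] (or plain string when `framework_only = FALSE`).
#' @param db named character vector of database sequences (or
#'   `Biostrings::AAStringSet`).
#' @param framework_only score the framework positions only.
#' @param top number of top matches averaged (default 20).
#' @return list of class `humanness_result`: `score`, `top_matches`
#'   (data frame db_id/identity sorted descending, at most `top` rows).
#' @export
t20_score <- function(query, db, framework_only = FALSE, top = 20) {
  if (inherits(db, "AAStringSet")) db <- as.character(db)
  db <- unlist(db)
  if (!length(db)) stopf("empty database")
  if (is.null(names(db))) names(db) <- paste0("db", seq_along(db))
  q <- humanness_query(query, framework_only)
  ids <- vapply(db, function(s) pairwise_identity(q, s), numeric(1))
  ord <- order(ids, decreasing = TRUE)
  k <- min(top, length(db))
  sel <- ord[seq_len(k)]
  structure(list(score = mean(ids[sel]),
                 top_matches = data.frame(db_id = names(db)[sel],
                                          identity = unname(ids[sel]),
                                          stringsAsFactors = FALSE),
                 framework_only = framework_only),
            class = "humanness_result")
}

#' @export
print.humanness_result <- function(x, ...) {
  cat(sprintf("<humanness_result> T20%s = %.1f (top %d matches)\n",
              if (x$framework_only) " (framework)" else " (CDR + framework)",
              x$score, nrow(x$top_matches)))
  invisible(x)
}

#' Full-length and framework-only T20 scores
#'
#' Convenience wrapper returning the pair of scores the humanness tables
#' report.
#'
#' @inheritParams t20_score
#' @return list with `t20_full`, `t20_framework`, and the two result objects.
#' @export
humanness_report <- function(query, db, top = 20) {
  full <- t20_score(query, db, framework_only = FALSE, top = top)
  fw <- t20_score(query, db, framework_only = TRUE, top = top)
  list(t20_full = full$score, t20_framework = fw$score,
       full = full, framework = fw)
}
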