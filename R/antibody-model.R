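# V-region sequences, region annotations and point-mutation notation

REGION_ORDER <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Construct an annotated V-region sequence
#'
#' A V-region is held as a plain one-letter amino-acid string together with a
#' per-position region label (framework segments FR1-FR4 and CDR1-CDR3).
#' Mutations are indexed by 1-based position in this mature sequence; no
#' Kabat/IMGT renumbering is performed, so region labels are annotations
#' supplied by the user (or a generator), never computed.
#'
#' @param residues one-letter amino-acid string.
#' @param chain_kind `"heavy"` or `"light"`.
#' @param region_map character vector, one label per position, drawn from
#'   FR1..FR4/CDR1..CDR3 and occurring in canonical order.
#' @param name free-text identifier.
#' @return an object of class `v_region`.
#' @export
v_region <- function(residues, chain_kind = c("heavy", "light"),
                     region_map = NULL, name = "") {
  chain_kind <- match.arg(chain_kind)
  res <- strsplit(toupper(residues), "")[[1]]
  if (length(res) == 0) stopf("empty sequence")
  bad <- !res %in% AA1
  if (any(bad)) stopf("non-standard amino-acid letter '%s' at position %d",
                      res[bad][1], which(bad)[1])
  if (is.null(region_map)) region_map <- rep("FR1", length(res))
  if (length(region_map) != length(res))
    stopf("region_map length %d != sequence length %d",
          length(region_map), length(res))
  if (!all(region_map %in% REGION_ORDER))
    stopf("unknown region label: %s",
          setdiff(region_map, REGION_ORDER)[1])
  runs <- rle(region_map)$values
  if (anyDuplicated(runs) || !identical(runs, REGION_ORDER[REGION_ORDER %in% runs]))
    stopf("region labels must occur once each, in canonical order FR1..FR4")
  structure(list(name = name, chain_kind = chain_kind,
                 residues = res, region_map = region_map),
            class = "v_region")
}

#' @export
print.v_region <- function(x, ...) {
  cat(sprintf("<v_region> %s (%s), %d aa\n", x$name, x$chain_kind,
              length(x$residues)))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.v_region <- function(x, ...) paste(x$residues, collapse = "")

#' Create a point mutation record
#'
#' @param chain `"HC"` or `"LC"`.
#' @param position 1-based position in the mature V-region.
#' @param wt_aa,mut_aa one-letter codes.
#' @param location free-text location label (e.g. `"Framework"`, `"CDR H2"`).
#' @param allow_identity permit `wt_aa == mut_aa` (used only for scanner
#'   self-tests).
#' @return object of class `point_mutation`.
#' @export
point_mutation <- function(chain, position, wt_aa, mut_aa, location = "",
                           allow_identity = FALSE) {
  if (!chain %in% c("HC", "LC")) stopf("chain must be HC or LC, got '%s'", chain)
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stopf("position must be >= 1")
  for (a in c(wt_aa, mut_aa))
    if (!a %in% AA1) stopf("non-standard amino-acid letter: '%s'", a)
  if (wt_aa == mut_aa && !allow_identity)
    stopf("identity mutation %s:%s%d%s not allowed", chain, wt_aa, position, mut_aa)
  structure(list(chain = chain, position = position, wt_aa = wt_aa,
                 mut_aa = mut_aa, location = location,
                 identity = wt_aa == mut_aa),
            class = "point_mutation")
}

#' Parse mutation notation such as "HC:G54I"
#'
#' Accepts `<HC|LC>:<wt><position><mut>` with optional whitespace after the
#' colon (the tables print e.g. `"LC: E1S"`).
#'
#' @inheritParams point_mutation
#' @param text mutation string.
#' @return a `point_mutation`.
#' @examples
#' parse_mutation("HC:G54I")
#' parse_mutation("LC: E1S")
#' @export
parse_mutation <- function(text, location = "", allow_identity = FALSE) {
  m <- regmatches(text, regexec("^\\s*(HC|LC):\\s*([A-Za-z])(\\d+)([A-Za-z])\\s*$",
                                text))[[1]]
  if (length(m) != 5) stopf("malformed mutation string: '%s'", text)
  wt <- toupper(m[3]); mu <- toupper(m[5]); pos <- as.integer(m[4])
  if (pos < 1L) stopf("position must be >= 1 in '%s'", text)
  point_mutation(m[2], pos, wt, mu, location = location,
                 allow_identity = allow_identity)
}

#' @export
format.point_mutation <- function(x, ...)
  sprintf("%s:%s%d%s", x$chain, x$wt_aa, x$position, x$mut_aa)

#' @export
print.point_mutation <- function(x, ...) {
  cat("<point_mutation>", format(x),
      if (nzchar(x$location)) paste0("[", x$location, "]") else "", "\n")
  invisible(x)
}

chain_kind_of <- function(chain) if (chain == "HC") "heavy" else "light"

#' Apply point mutations to a V-region sequence
#'
#' @param seq a [v_region()].
#' @param muts list of [point_mutation()]s on the matching chain.
#' @return mutated `v_region`; the region map is unchanged.
#' @export
apply_mutations <- function(seq, muts) {
  stopifnot(inherits(seq, "v_region"))
  if (inherits(muts, "point_mutation")) muts <- list(muts)
  pos <- vapply(muts, function(m) m$position, integer(1))
  if (anyDuplicated(pos)) stopf("duplicate mutation positions: %d",
                                pos[duplicated(pos)][1])
  res <- seq$residues
  for (m in muts) {
    if (chain_kind_of(m$chain) != seq$chain_kind)
      stopf("mutation %s targets a %s chain but sequence is %s",
            format(m), chain_kind_of(m$chain), seq$chain_kind)
    if (m$position > length(res))
      stopf("position %d beyond sequence length %d", m$position, length(res))
    found <- res[m$position]
    if (found != m$wt_aa)
      stopf("wild-type mismatch at position %d: expected %s, found %s",
            m$position, m$wt_aa, found)
    res[m$position] <- m$mut_aa
  }
  out <- seq
  out$residues <- res
  out
}

#' Enumerate the substitutions separating two equal-length V-regions
#'
#' Inverse of [apply_mutations()]: applying the returned list to `a` yields
#' `b`.  The list is sorted by position.
#'
#' @param a,b `v_region`s of equal length and chain kind.
#' @return list of `point_mutation`.
#' @export
diff_sequences <- function(a, b) {
  stopifnot(inherits(a, "v_region"), inherits(b, "v_region"))
  if (a$chain_kind != b$chain_kind) stopf("chain kinds differ")
  if (length(a$residues) != length(b$residues))
    stopf("length mismatch: %d vs %d", length(a$residues), length(b$residues))
  chain <- if (a$chain_kind == "heavy") "HC" else "LC"
  idx <- which(a$residues != b$residues)
  lapply(idx, function(i)
    point_mutation(chain, i, a$residues[i], b$residues[i]))
}

#' Read V-region sequences from FASTA
#'
#' The description line carries the name and chain kind as
#' `"name|heavy"` / `"name|light"`.  Region maps can be attached from an
#' annotation table via [read_region_annotations()].
#'
#' @param file FASTA path.
#' @param regions optional region annotation data frame
#'   (columns chain, start, end, label).
#' @return list of `v_region`.
#' @export
read_vregion_fasta <- function(file, regions = NULL) {
  ss <- Biostrings::readAAStringSet(file)
  out <- lapply(seq_along(ss), function(i) {
    desc <- names(ss)[i]
    parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
    kind <- if (length(parts) >= 2) trimws(parts[2]) else "heavy"
    if (!kind %in% c("heavy", "light"))
      stopf("FASTA description '%s' lacks a |heavy / |light tag", desc)
    rmap <- NULL
    if (!is.null(regions)) {
      sub <- regions[regions$chain == kind, , drop = FALSE]
      if (nrow(sub)) {
        rmap <- rep(NA_character_, nchar(as.character(ss[[i]])))
        for (k in seq_len(nrow(sub)))
          rmap[sub$start[k]:sub$end[k]] <- sub$label[k]
        if (anyNA(rmap)) stopf("region annotation does not cover every position")
      }
    }
    v_region(as.character(ss[[i]]), kind, region_map = rmap,
             name = trimws(parts[1]))
  })
  names(out) <- vapply(out, function(v) v$name, character(1))
  out
}

#' Write V-region sequences to FASTA
#'
#' @param seqs list of `v_region`.
#' @param file output path.
#' @export
write_vregion_fasta <- function(seqs, file) {
  if (inherits(seqs, "v_region")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, function(v) paste0(v$name, "|", v$chain_kind),
                      character(1))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Read a region-annotation table (columns chain, start, end, label)
#' @param file CSV path.
#' @return data frame.
#' @export
read_region_annotations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chain", "start", "end", "label")
  if (!all(need %in% names(df)))
    stopf("region annotation file must have columns %s", paste(need, collapse = ", "))
  df
}
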