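#' Transcript coding model
#'
#' Minimal transcript description for exon-skip consequence prediction:
#' ordered exons with their coding lengths in nucleotides (no genome
#' coordinates needed).
#'
#' @param transcript_id Identifier.
#' @param exons Data frame with columns `exon_number` (strictly
#'   increasing) and `coding_length_nt` (>= 0).
#' @param cds_frame_offset Reading-frame offset of the first listed exon
#'   (0-2).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exons, cds_frame_offset = 0) {
  stopifnot(all(c("exon_number", "coding_length_nt") %in% names(exons)))
  if (any(diff(exons$exon_number) <= 0))
    stop("exon numbers must be strictly increasing")
  if (any(exons$coding_length_nt < 0)) stop("coding lengths must be >= 0")
  if (!cds_frame_offset %in% 0:2) stop("cds_frame_offset must be 0, 1 or 2")
  structure(list(transcript_id = transcript_id, exons = exons,
                 cds_frame_offset = as.integer(cds_frame_offset)),
            class = "transcript_model")
}

#' Read a transcript model from JSON
#'
#' Expects `{"transcript_id": ..., "exons": [[number, length], ...],
#' "cds_frame_offset": ...}`.
#'
#' @param path JSON file path.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  exons <- as.data.frame(j$exons)
  names(exons) <- c("exon_number", "coding_length_nt")
  transcript_model(j$transcript_id, exons,
                   if (is.null(j$cds_frame_offset)) 0 else j$cds_frame_offset)
}

#' Predict the protein consequence of skipping exons
#'
#' Sums the coding lengths of the skipped exons; a multiple of 3 is an
#' in-frame deletion of `nt_removed / 3` amino acids, anything else is a
#' frameshift starting at codon `ceiling(preceding_nt / 3) + 1`, where
#' `preceding_nt` counts coding nucleotides before the first skipped exon.
#'
#' @param model A [transcript_model()].
#' @param skipped_exon_numbers Integer vector of exon numbers present in
#'   the model.
#' @return An object of class `skip_effect`: `nt_removed`, `in_frame`,
#'   `aa_removed` (iff in frame), `frameshift_position` (iff frameshift).
#' @examples
#' m <- transcript_model("tx", data.frame(exon_number = 6:8,
#'                                        coding_length_nt = c(117, 96, 90)))
#' predict_exon_skip_effect(m, 6:8)  # in-frame loss of 101 aa
#' @export
predict_exon_skip_effect <- function(model, skipped_exon_numbers) {
  stopifnot(inherits(model, "transcript_model"))
  unknown <- setdiff(skipped_exon_numbers, model$exons$exon_number)
  if (length(unknown) > 0)
    stop("unknown exon number(s): ", paste(unknown, collapse = ", "))
  sel <- model$exons$exon_number %in% skipped_exon_numbers
  nt <- sum(model$exons$coding_length_nt[sel])
  in_frame <- nt %% 3 == 0
  out <- list(transcript_id = model$transcript_id,
              skipped = sort(unique(skipped_exon_numbers)),
              nt_removed = nt, in_frame = in_frame,
              aa_removed = if (in_frame) nt / 3 else NA_integer_,
              frameshift_position = NA_integer_)
  if (!in_frame) {
    before <- model$exons$exon_number < min(skipped_exon_numbers)
    preceding_nt <- sum(model$exons$coding_length_nt[before]) +
      model$cds_frame_offset
    out$frameshift_position <- ceiling(preceding_nt / 3) + 1
  }
  structure(out, class = "skip_effect")
}

#' @export
print.skip_effect <- function(x, ...) {
  if (x$in_frame)
    cat(sprintf("Skip of exon(s) %s: %d nt removed, in frame, %d aa deleted\n",
                paste(x$skipped, collapse = ","), x$nt_removed, x$aa_removed))
  else
    cat(sprintf("Skip of exon(s) %s: %d nt removed, frameshift at codon %d\n",
                paste(x$skipped, collapse = ","), x$nt_removed,
                x$frameshift_position))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Global (Needleman-Wunsch) alignment of two protein sequences
#'
#' Optimal-score global alignment by dynamic programming with linear gap
#' penalty and a deterministic traceback tie-break: diagonal is preferred
#' over up (gap in the second sequence), which is preferred over left.
#' Scoring is configurable either as match/mismatch values or as a full
#' substitution matrix (e.g. BLOSUM62 from
#' `Biostrings: data(BLOSUM62)`).
#'
#' @param a,b Amino-acid strings over the 20-letter alphabet plus `X`
#'   (either may be empty, giving an all-gap alignment).
#' @param match,mismatch Scores used when no substitution matrix is given
#'   (defaults 1 / 0).
#' @param gap Linear gap penalty per gapped position (default -1).
#' @param substitution Optional substitution matrix with residue dimnames.
#' @return An object of class `protein_alignment`: `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1,
                         substitution = NULL) {
  av <- if (nchar(a) > 0) strsplit(toupper(a), "")[[1]] else character(0)
  bv <- if (nchar(b) > 0) strsplit(toupper(b), "")[[1]] else character(0)
  bad <- setdiff(c(av, bv), .AA_ALPHABET)
  if (length(bad) > 0)
    stop("illegal residue character(s): ", paste(unique(bad), collapse = ", "))
  n <- length(av); m <- length(bv)
  sub_score <- function(x, y) {
    if (!is.null(substitution)) substitution[x, y]
    else if (x == y) match else mismatch
  }
  s <- matrix(0, n + 1, m + 1)
  ptr <- matrix(0L, n + 1, m + 1)          # 1 diag, 2 up, 3 left
  s[, 1] <- gap * (0:n); s[1, ] <- gap * (0:m)
  ptr[-1, 1] <- 2L; ptr[1, -1] <- 3L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- c(s[i, j] + sub_score(av[i], bv[j]),
                s[i, j + 1] + gap,
                s[i + 1, j] + gap)
      k <- which.max(cand)                 # earliest max: diag > up > left
      s[i + 1, j + 1] <- cand[k]
      ptr[i + 1, j + 1] <- k
    }
  }
  ai <- character(0); bi <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    k <- ptr[i, j]
    if (k == 1L) {
      ai <- c(av[i - 1], ai); bi <- c(bv[j - 1], bi); i <- i - 1; j <- j - 1
    } else if (k == 2L) {
      ai <- c(av[i - 1], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1], bi); j <- j - 1
    }
  }
  structure(list(aligned_a = paste(ai, collapse = ""),
                 aligned_b = paste(bi, collapse = ""),
                 score = s[n + 1, m + 1]),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Global alignment (score", x$score, "):\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Percent identity over a query window of an alignment
#'
#' Over the alignment columns whose query (first sequence) residue index
#' lies in `[start, end]`: `100 * matching columns / columns with a query
#' residue`, rounded to the nearest integer. Coordinates are 1-based
#' inclusive positions on the ungapped query.
#'
#' @param alignment A [global_align()] result.
#' @param start,end Query window (1 <= start <= end <= query length).
#' @return Integer percent identity in `[0, 100]`.
#' @export
signature_identity <- function(alignment, start, end) {
  stopifnot(inherits(alignment, "protein_alignment"))
  if (start < 1 || end < start) stop("need 1 <= start <= end")
  av <- strsplit(alignment$aligned_a, "")[[1]]
  bv <- strsplit(alignment$aligned_b, "")[[1]]
  qidx <- cumsum(av != "-")
  qlen <- if (length(qidx)) max(qidx) else 0
  if (end > qlen) stop("window extends past the query (length ", qlen, ")")
  in_win <- av != "-" & qidx >= start & qidx <= end
  n_cols <- sum(in_win)
  n_match <- sum(in_win & av == bv)
  round(100 * n_match / n_cols)
}
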