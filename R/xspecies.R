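#' Join human and mouse DE results through 1:1 orthologs
#'
#' Inner join of per-species stage-profile tables through the ortholog
#' map, keeping only unambiguous 1:1 pairs (rows whose `mapping_type` is
#' not `one2one`, or whose human or mouse id occurs more than once in the
#' map, are dropped; the counts are recorded in attributes).
#'
#' @param human,mouse Data frames keyed by `gene_id` (typically
#'   [species_profiles()] output).
#' @param map Data frame with columns `human_id`, `mouse_id` and
#'   optionally `mapping_type`.
#' @return A data frame with `human_id`, `mouse_id` and the two tables'
#'   columns suffixed `_human` / `_mouse`; attributes `n_dropped_non11`
#'   (non-1:1 map rows) and `n_unmatched` (1:1 pairs absent from a table).
#' @export
join_orthologs <- function(human, mouse, map) {
  stopifnot("gene_id" %in% names(human), "gene_id" %in% names(mouse),
            all(c("human_id", "mouse_id") %in% names(map)))
  ok <- rep(TRUE, nrow(map))
  if ("mapping_type" %in% names(map)) ok <- map$mapping_type == "one2one"
  ok <- ok & !(map$human_id %in% map$human_id[duplicated(map$human_id)]) &
    !(map$mouse_id %in% map$mouse_id[duplicated(map$mouse_id)])
  n_non11 <- sum(!ok)
  map11 <- map[ok, c("human_id", "mouse_id")]
  hm <- merge(map11, human, by.x = "human_id", by.y = "gene_id")
  hmm <- merge(hm, mouse, by.x = "mouse_id", by.y = "gene_id",
               suffixes = c("_human", "_mouse"))
  if (nrow(hmm) == 0)
    stop("no ortholog pair is present in both tables")
  out <- hmm[, c("human_id", "mouse_id",
                 setdiff(names(hmm), c("human_id", "mouse_id")))]
  out <- out[order(out$human_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_non11") <- n_non11
  attr(out, "n_unmatched") <- nrow(map11) - nrow(out)
  out
}

#' Classify per-stage regulation calls
#'
#' A stage call is `"up"` when `log2fc > lfc_min` and `q < q_max`,
#' `"down"` when `log2fc < -lfc_min` and `q < q_max`, otherwise `"ns"`.
#'
#' @param log2fc,q Numeric vectors (recycled together).
#' @param lfc_min Log2 fold-change threshold (default 1).
#' @param q_max FDR threshold (default 0.05).
#' @return Character vector of calls.
#' @examples
#' classify_direction(c(1.6, 0.2, 1.5), c(0.01, 0.01, 0.2))
#' @export
classify_direction <- function(log2fc, q, lfc_min = 1, q_max = 0.05) {
  ifelse(q < q_max & log2fc > lfc_min, "up",
         ifelse(q < q_max & log2fc < -lfc_min, "down", "ns"))
}

#' Per-species stage profiles from two DE tables
#'
#' Combines the early-stage (CH-like) and late-stage (HF-like) DE tables
#' of one species into a per-gene profile with direction calls at both
#' stages.
#'
#' @param de_ch,de_hf [de_table()]s for the early and late contrast.
#' @param lfc_min,q_max Thresholds for [classify_direction()].
#' @return Data frame: `gene_id`, `log2fc_ch`, `q_ch`, `log2fc_hf`,
#'   `q_hf`, `direction_ch`, `direction_hf`.
#' @export
species_profiles <- function(de_ch, de_hf, lfc_min = 1, q_max = 0.05) {
  m <- merge(de_ch[, c("gene_id", "log2fc", "q_value")],
             de_hf[, c("gene_id", "log2fc", "q_value")],
             by = "gene_id", suffixes = c("_ch", "_hf"))
  data.frame(gene_id = m$gene_id,
             log2fc_ch = m$log2fc_ch, q_ch = m$q_value_ch,
             log2fc_hf = m$log2fc_hf, q_hf = m$q_value_hf,
             direction_ch = classify_direction(m$log2fc_ch, m$q_value_ch,
                                               lfc_min, q_max),
             direction_hf = classify_direction(m$log2fc_hf, m$q_value_hf,
                                               lfc_min, q_max))
}

#' Classify one gene's stage profile
#'
#' @param record A list or one-row data frame with `log2fc_ch`, `q_ch`,
#'   `log2fc_hf`, `q_hf` (both contrasts required).
#' @inheritParams classify_direction
#' @return Named character vector `c(direction_ch = ..., direction_hf = ...)`.
#' @export
classify_profile <- function(record, lfc_min = 1, q_max = 0.05) {
  need <- c("log2fc_ch", "q_ch", "log2fc_hf", "q_hf")
  if (!all(need %in% names(record)))
    stop("record must carry both contrasts: ",
         paste(setdiff(need, names(record)), collapse = ", "))
  c(direction_ch = classify_direction(record$log2fc_ch, record$q_ch,
                                      lfc_min, q_max),
    direction_hf = classify_direction(record$log2fc_hf, record$q_hf,
                                      lfc_min, q_max))
}

#' Extract the cross-species conserved gene set
#'
#' Keeps ortholog pairs whose human and mouse per-stage direction patterns
#' are identical and not (ns, ns); the shared pattern becomes the profile
#' class (e.g. `"up-up"` for progressively upregulated genes). The
#' accompanying heatmap matrix holds the log2 fold changes over the four
#' contrasts, rows ordered by profile class and then by decreasing mean
#' absolute log2 fold change.
#'
#' @param paired Output of [join_orthologs()] applied to two
#'   [species_profiles()] tables.
#' @param require_stages `"pattern"` (default): human and mouse calls must
#'   match at each stage; `"all"`: additionally both stages must be
#'   significant; `"any"`: patterns match and at least one stage is
#'   significant (implied by excluding (ns, ns)).
#' @return An object of class `conserved_gene_set`: `entries` (data frame
#'   with ids, class and per-contrast log2fc) and `heatmap` (genes x 4
#'   matrix: `human_CH`, `human_HF`, `mouse_CH`, `mouse_HF`).
#' @export
conserved_set <- function(paired, require_stages = c("pattern", "all", "any")) {
  require_stages <- match.arg(require_stages)
  same <- paired$direction_ch_human == paired$direction_ch_mouse &
    paired$direction_hf_human == paired$direction_hf_mouse
  n_sig <- (paired$direction_ch_human != "ns") +
    (paired$direction_hf_human != "ns")
  keep <- same & switch(require_stages,
                        pattern = n_sig >= 1,
                        any = n_sig >= 1,
                        all = n_sig == 2)
  e <- paired[keep, , drop = FALSE]
  cls <- paste(e$direction_ch_human, e$direction_hf_human, sep = "-")
  entries <- data.frame(human_gene = e$human_id, mouse_gene = e$mouse_id,
                        class = cls,
                        log2fc_human_ch = e$log2fc_ch_human,
                        log2fc_human_hf = e$log2fc_hf_human,
                        log2fc_mouse_ch = e$log2fc_ch_mouse,
                        log2fc_mouse_hf = e$log2fc_hf_mouse)
  hm <- as.matrix(entries[, c("log2fc_human_ch", "log2fc_human_hf",
                              "log2fc_mouse_ch", "log2fc_mouse_hf")])
  colnames(hm) <- c("human_CH", "human_HF", "mouse_CH", "mouse_HF")
  rownames(hm) <- entries$human_gene
  ord <- order(entries$class, -rowMeans(abs(hm)))
  entries <- entries[ord, , drop = FALSE]
  hm <- hm[ord, , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, heatmap = hm), class = "conserved_gene_set")
}

#' @export
print.conserved_gene_set <- function(x, ...) {
  cat(sprintf("Conserved gene set: %d ortholog pairs\n", nrow(x$entries)))
  if (nrow(x$entries) > 0) print(table(x$entries$class))
  invisible(x)
}

#' @export
length.conserved_gene_set <- function(x) nrow(x$entries)

#' Export the conserved-set heatmap matrix as TSV
#'
#' @param set A [conserved_set()] result (non-empty).
#' @param path Output TSV path; rows are genes, columns the four
#'   contrasts' log2 fold changes.
#' @return `path`, invisibly.
#' @export
export_heatmap_matrix <- function(set, path) {
  stopifnot(inherits(set, "conserved_gene_set"))
  if (nrow(set$entries) == 0) stop("conserved set is empty; nothing to export")
  df <- data.frame(gene = rownames(set$heatmap), set$heatmap,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
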