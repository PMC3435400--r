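#' Build a methylation signature set from a differential result
#'
#' The signature is the set of called probes of one comparison, each
#' annotated with its methylation direction in the first-named group
#' (`more_methylated` for positive `z_diff`), plus the derived gene set
#' (via the target-ID grammar when target IDs are available).
#'
#' @param records a `differential_result` (or compatible data.frame with
#'   `probe_id`, `z_diff` and `called` columns).
#' @param name signature name.
#' @param manifest optional `probe_manifest` supplying target IDs when
#'   `records` lacks them.
#' @return Object of class `signature_set`: list with `name`, `cpg_ids`,
#'   `direction_of` (named character vector over `cpg_ids`), `genes`, and
#'   a `table` data.frame (`probe_id`, `target_id`, `gene`, `direction`).
#' @export
build_signature <- function(records, name, manifest = NULL) {
  need <- c("probe_id", "z_diff", "called")
  if (!all(need %in% names(records)))
    stop("'records' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  hit <- records[records$called, , drop = FALSE]
  target_id <- if ("target_id" %in% names(hit)) hit$target_id
  else if (!is.null(manifest)) manifest$target_id[match(hit$probe_id,
                                                        manifest$probe_id)]
  else rep(NA_character_, nrow(hit))
  gene <- rep(NA_character_, nrow(hit))
  ok <- !is.na(target_id)
  if (any(ok)) gene[ok] <- parse_target_id(target_id[ok])$gene
  direction <- ifelse(hit$z_diff > 0, "more_methylated", "less_methylated")
  tab <- data.frame(probe_id = hit$probe_id, target_id = target_id,
                    gene = gene, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(name = name, cpg_ids = hit$probe_id,
                 direction_of = stats::setNames(direction, hit$probe_id),
                 genes = unique(gene[!is.na(gene)]), table = tab),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature '%s': %d CpG sites across %d genes (%d more / %d less methylated)\n",
              x$name, length(x$cpg_ids), length(x$genes),
              sum(x$direction_of == "more_methylated"),
              sum(x$direction_of == "less_methylated")))
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$cpg_ids)

#' Three-way Venn decomposition of signature sets
#'
#' Partitions three named signature sets into the seven Venn regions:
#' the three-way `core`, the members `unique` to each set, and the three
#' `pairwise_only` regions.  Per set, the counts reconcile:
#' size = core + two pairwise regions + unique.
#'
#' @param sets named list of exactly three `signature_set` objects (or
#'   plain character vectors of probe IDs).
#' @return list with `core` (character vector), `unique_per_name` (named
#'   list), `pairwise_only` (named list, names like `"a&b"`), and
#'   `counts` (data.frame `set`, `size`, `core`, `pairwise`, `unique`).
#' @export
venn_decompose <- function(sets) {
  if (length(sets) != 3L || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("'sets' must be a named list of exactly three sets", call. = FALSE)
  ids <- lapply(sets, function(s)
    unique(if (inherits(s, "signature_set")) s$cpg_ids else as.character(s)))
  nm <- names(ids)
  core <- Reduce(intersect, ids)
  uniq <- lapply(seq_along(ids), function(i)
    setdiff(ids[[i]], union(ids[[setdiff(1:3, i)[1L]]],
                            ids[[setdiff(1:3, i)[2L]]])))
  names(uniq) <- nm
  pair_idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pairwise <- lapply(pair_idx, function(ij)
    setdiff(intersect(ids[[ij[1L]]], ids[[ij[2L]]]), core))
  names(pairwise) <- vapply(pair_idx, function(ij)
    paste(nm[ij], collapse = "&"), character(1))
  counts <- data.frame(
    set = nm,
    size = vapply(ids, length, integer(1)),
    core = length(core),
    pairwise = vapply(1:3, function(i)
      sum(vapply(seq_along(pair_idx), function(k)
        if (i %in% pair_idx[[k]]) length(pairwise[[k]]) else 0L,
        integer(1))), integer(1)),
    unique = vapply(uniq, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(core = core, unique_per_name = uniq, pairwise_only = pairwise,
       counts = counts)
}

#' Right-tailed hypergeometric (Fisher) functional enrichment
#'
#' For each function label in the annotation, tests whether the signature's
#' genes are over-represented among the reference genes annotated to that
#' function: with `N_ref` reference genes, `K_ref` of them annotated,
#' and `n_sig` signature genes, the p-value is `P(X >= k_in)` for
#' `X ~ Hypergeometric(N_ref, K_ref, n_sig)` — the right tail of Fisher's
#' exact test.  A gene with several signature CpGs counts once.  The
#' analyzed panel itself is the intended reference universe, which avoids
#' bias from the panel's gene composition.
#'
#' @param signature a `signature_set`, or a character vector of gene
#'   symbols.
#' @param annotation data.frame mapping `gene` to `function_label` (one
#'   pair per row); genes outside the reference are ignored.
#' @param reference_genes character vector: the gene universe (must
#'   contain the signature genes).
#' @param adjust if `TRUE`, append Benjamini-Hochberg adjusted p-values
#'   (raw Fisher p is the default report).
#' @return data.frame of class `enrichment_result`, sorted by ascending
#'   p: `function_label`, `k_in`, `n_sig`, `K_ref`, `N_ref`, `p_value`,
#'   `neg_log10_p` (and `p_adjusted` when requested).
#' @export
fisher_enrichment <- function(signature, annotation, reference_genes,
                              adjust = FALSE) {
  sig_genes <- unique(if (inherits(signature, "signature_set"))
    signature$genes else as.character(signature))
  reference_genes <- unique(as.character(reference_genes))
  if (length(reference_genes) == 0L)
    stop("empty reference gene universe", call. = FALSE)
  if (!all(sig_genes %in% reference_genes))
    stop("signature genes must be a subset of the reference universe",
         call. = FALSE)
  if (!all(c("gene", "function_label") %in% names(annotation)))
    stop("'annotation' needs columns 'gene' and 'function_label'",
         call. = FALSE)
  ann <- annotation[annotation$gene %in% reference_genes, , drop = FALSE]
  N <- length(reference_genes)
  n <- length(sig_genes)
  labs <- unique(ann$function_label)
  res <- do.call(rbind, lapply(labs, function(f) {
    genes_f <- unique(ann$gene[ann$function_label == f])
    K <- length(genes_f)
    k <- length(intersect(sig_genes, genes_f))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(function_label = f, k_in = k, n_sig = n, K_ref = K,
               N_ref = N, p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(function_label = character(), k_in = integer(),
                      n_sig = integer(), K_ref = integer(),
                      N_ref = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$function_label), , drop = FALSE]
  res$neg_log10_p <- -log10(pmax(res$p_value, 1e-300))
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Heatmap export: z-score matrix restricted to a signature
#'
#' Rows are the signature's CpGs, columns the samples ordered by cell type
#' then phenotype (then sample ID), matching the usual two-block heatmap
#' layout of matched-tissue studies.
#'
#' @param Z a Z-scale `methylation_matrix`.
#' @param signature a `signature_set`.
#' @param samples a `sample_sheet` describing the columns of `Z`.
#' @return numeric matrix (signature CpGs x reordered samples).
#' @export
signature_heatmap_matrix <- function(Z, signature, samples) {
  V <- if (inherits(Z, "methylation_matrix")) Z$values else Z
  ids <- intersect(signature$cpg_ids, rownames(V))
  ord <- order(samples$cell_type, samples$phenotype, samples$sample_id)
  V[ids, samples$sample_id[ord], drop = FALSE]
}
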