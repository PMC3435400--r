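#' Parse panel target IDs
#'
#' GoldenGate-style methylation panels identify each CpG probe by a *target
#' ID* of the form `GENE_[E|P]<distance>_[F|R]`, e.g. `STAT5A_E42_F`: the
#' gene symbol, a region-context token (`E` exon-1 / `P` promoter) followed
#' by the distance in bases to the transcription start site, and the
#' reference strand (`F`/`R`).  Gene symbols may themselves contain
#' underscores, so parsing is right-anchored: only the final two
#' underscore-delimited tokens are structural.
#'
#' @param target_id character vector of target IDs.
#' @return A data.frame with one row per ID and columns `gene`,
#'   `region_class` (`"E"` or `"P"`), `tss_distance` (integer, bases) and
#'   `strand` (`"F"` or `"R"`).
#' @examples
#' parse_target_id("STAT5A_E42_F")
#' parse_target_id(c("CRIP1_P874_R", "IGSF4C_E65_F"))
#' @seealso [format_target_id()] for the inverse.
#' @export
parse_target_id <- function(target_id) {
  if (length(target_id) == 0L) {
    return(data.frame(gene = character(), region_class = character(),
                      tss_distance = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  if (!is.character(target_id) || anyNA(target_id) || any(!nzchar(target_id)))
    stop("'target_id' must be non-empty character strings", call. = FALSE)

  parts <- strsplit(target_id, "_", fixed = TRUE)
  out <- vapply(seq_along(parts), function(i) {
    tok <- parts[[i]]
    id <- target_id[i]
    if (length(tok) < 3L)
      stop(sprintf("malformed target ID '%s': expected GENE_[EP]<n>_[FR]", id),
           call. = FALSE)
    strand <- tok[length(tok)]
    region <- tok[length(tok) - 1L]
    gene <- paste(tok[seq_len(length(tok) - 2L)], collapse = "_")
    if (!strand %in% c("F", "R"))
      stop(sprintf("malformed strand token '%s' in target ID '%s'", strand, id),
           call. = FALSE)
    if (!grepl("^[EP][0-9]+$", region))
      stop(sprintf("malformed region token '%s' in target ID '%s'", region, id),
           call. = FALSE)
    if (!nzchar(gene))
      stop(sprintf("empty gene symbol in target ID '%s'", id), call. = FALSE)
    c(gene, substr(region, 1L, 1L), substr(region, 2L, nchar(region)), strand)
  }, character(4))

  data.frame(gene = out[1L, ],
             region_class = out[2L, ],
             tss_distance = as.integer(out[3L, ]),
             strand = out[4L, ],
             stringsAsFactors = FALSE)
}

#' Format panel target IDs
#'
#' Inverse of [parse_target_id()]: `parse_target_id(format_target_id(...))`
#' is the identity for valid fields.
#'
#' @param gene gene symbol(s); may contain underscores.
#' @param region_class `"E"` or `"P"`.
#' @param tss_distance non-negative integer distance to the TSS, bases.
#' @param strand `"F"` or `"R"`.
#' @return character vector of target IDs.
#' @export
format_target_id <- function(gene, region_class, tss_distance, strand) {
  if (any(!nzchar(gene))) stop("empty gene symbol", call. = FALSE)
  if (!all(region_class %in% c("E", "P")))
    stop("region_class must be 'E' or 'P'", call. = FALSE)
  if (!all(strand %in% c("F", "R")))
    stop("strand must be 'F' or 'R'", call. = FALSE)
  d <- as.integer(tss_distance)
  if (anyNA(d) || any(d < 0))
    stop("tss_distance must be a non-negative integer", call. = FALSE)
  paste0(gene, "_", region_class, d, "_", strand)
}
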