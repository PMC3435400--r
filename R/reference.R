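#' Published validation targets for the GSE37853 study design
#'
#' The study deposited under GEO accession GSE37853 (Illumina GoldenGate
#' Methylation Cancer Panel I; matched AEC/PBMC samples from 25 children)
#' reported a specific set of signature counts and per-CpG statistics.
#' These are *accession-dependent* validation targets: they can only be
#' reproduced by running the pipeline on the real deposited data, not on
#' synthetic datasets, whose probe content and effect placement are
#' random.  They are provided so that a user who converts the GSE37853
#' series to this package's input format can check the pipeline output
#' against the published analysis.
#'
#' @return list with elements
#' \describe{
#'   \item{filter}{data.frame of probe-filter counts (1505 input; 84 X
#'     chromosome, 272 SNP-containing, 122 detection-failing; 1027
#'     retained across 671 genes).}
#'   \item{signature_counts}{data.frame of reported signature sizes: 80
#'     AEC-vs-PBMC sites over all subjects; 96/71/89 within
#'     healthy/atopic/asthmatic; 57 core sites across 47 genes; 13/8/6
#'     unique to healthy/atopic/asthmatic; 8 atopic-vs-asthmatic AEC
#'     sites; 0 phenotype differences in PBMCs.}
#'   \item{atopic_vs_asthmatic_aec}{data.frame of the eight CpG sites
#'     called between atopic and asthmatic AECs, with the reported
#'     log2 z-score difference (atopic relative to asthmatic) and
#'     q-value.}
#' }
#' @export
reference_results_gse37853 <- function() {
  filter <- data.frame(
    category = c("input", "x_chromosome", "snp_in_probe", "detection",
                 "retained"),
    n = c(1505L, 84L, 272L, 122L, 1027L),
    stringsAsFactors = FALSE)
  signature_counts <- data.frame(
    quantity = c("celltype_all_sites", "celltype_all_genes",
                 "celltype_healthy_sites", "celltype_atopic_sites",
                 "celltype_asthmatic_sites", "core_sites", "core_genes",
                 "unique_healthy", "unique_atopic", "unique_asthmatic",
                 "aec_atopic_vs_asthmatic_sites",
                 "pbmc_phenotype_sites"),
    n = c(80L, 67L, 96L, 71L, 89L, 57L, 47L, 13L, 8L, 6L, 8L, 0L),
    stringsAsFactors = FALSE)
  atopic_vs_asthmatic_aec <- data.frame(
    target_id = c("CRIP1_P874_R", "FGFR1_P204_F", "STAT5A_E42_F",
                  "S100A2_P1186_F", "ITGA2_P26_R", "EGR4_E70_F",
                  "ID1_P880_F", "IGSF4C_E65_F"),
    z_diff_log2 = c(-1.14, -1.11, -1.01, 1.03, -1.07, -1.31, -1.03, -1.09),
    q_value = c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02, 0.04, 0.04),
    stringsAsFactors = FALSE)
  list(filter = filter, signature_counts = signature_counts,
       atopic_vs_asthmatic_aec = atopic_vs_asthmatic_aec)
}
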