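#' Built-in metabolic pathway gene sets
#'
#' Two gene sets emulating the MSigDB Reactome pathways used for metabolic
#' subtyping: a 29-gene glycolysis set and a 24-gene cholesterol
#' biosynthesis set. The membership is a synthetic stand-in assembled from
#' canonical pathway member symbols at the documented sizes; it is NOT a
#' verbatim copy of any MSigDB release (see the shipped
#' `extdata/metabolic_gene_sets.synthetic.gmt`).
#'
#' @return list of two [gene_set()] objects named
#'   `REACTOME_GLYCOLYSIS` and `REACTOME_CHOLESTEROL_BIOSYNTHESIS`.
#' @export
default_gene_sets <- function() {
  gly <- c("ENO1", "ENO2", "ENO3", "PFKFB3", "PFKFB4", "HK1", "HK2", "GPI",
           "PFKL", "PFKM", "ALDOA", "ALDOB", "ALDOC", "TPI1", "GAPDH",
           "PGK1", "PGAM1", "PKM", "LDHA", "SLC2A1", "SLC2A3", "PDK1",
           "PDK3", "PGM1", "ADPGK", "GALM", "PMM2", "FBP1", "DLD")
  chol <- c("HMGCR", "HMGCS1", "SQLE", "NSDHL", "LSS", "FDFT1", "FDPS",
            "GGPS1", "IDI1", "MVD", "MVK", "PMVK", "CYP51A1", "DHCR7",
            "DHCR24", "EBP", "SC5D", "MSMO1", "TM7SF2", "ACAT2", "LBR",
            "STARD4", "SREBF2", "INSIG1")
  stopifnot(length(gly) == 29L, length(chol) == 24L)
  list(gene_set("REACTOME_GLYCOLYSIS", gly),
       gene_set("REACTOME_CHOLESTEROL_BIOSYNTHESIS", chol))
}
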