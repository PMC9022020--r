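## Small reference tables shipped as code.

#' Read counts of the public cohorts the method was developed on
#'
#' Per-dataset totals of downloaded metagenomic sequencing reads for the
#' four public longitudinal stool cohorts commonly used to exercise this
#' workflow: high-density sampling of healthy adults pre bowel wash
#' (Fukuyama et al., PRJNA388263), a pre/post single-antibiotic cohort
#' (Raymond et al., PRJEB8094), the NIH Human Microbiome Project paired
#' samples, and hospitalized COVID-19 patients (Zuo et al.,
#' PRJNA624223).  These accessions document provenance only; no download
#' is performed.
#'
#' @return data.frame with columns `dataset`, `accession`, `reads`.
#'   The four totals sum to 6,390,986,972 reads.
#' @export
#' @examples
#' sum(cohort_read_counts()$reads)
cohort_read_counts <- function() {
  data.frame(
    dataset = c("Fukuyama", "Raymond", "HMP", "Zuo"),
    accession = c("PRJNA388263", "PRJEB8094", "portal.hmpdacc.org",
                  "PRJNA624223"),
    reads = c(359276476, 1500234831, 4124040250, 407435415)
  )
}
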