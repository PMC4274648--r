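# Construct a minimal valid cohort in code: one row per element of `hu`,
# defaults all-normal profile; attenuation_degree is always derived from HU.
makeCohort <- function(hu, dtd = FALSE,
                       attPattern = "homogeneous", size = "normal",
                       margin = "smooth", enhPattern = "homogeneous",
                       enhOffset = 88.2) {
  n <- length(hu)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    histopath_class = ifelse(rep_len(dtd, n), "hashimoto", "normal"),
    hu_nonenhanced = hu,
    hu_enhanced = hu + enhOffset,
    attenuation_degree = as.character(classifyAttenuationDegree(hu)),
    attenuation_pattern = rep_len(attPattern, n),
    size_category = rep_len(size, n),
    margin = rep_len(margin, n),
    enhancement_pattern = rep_len(enhPattern, n),
    stringsAsFactors = FALSE
  )
}
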