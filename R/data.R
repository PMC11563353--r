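#' Clinical cohort lesion distribution
#'
#' The distribution of the 67 imaged oral lesions of the reference clinical
#' cohort by anatomical site and histopathology grade (benign, moderate
#' dysplasia, high-grade dysplasia, squamous cell carcinoma), shipped as a
#' plain-text table in `inst/extdata/lesion_distribution.csv`.
#'
#' @return Data frame with columns `site`, `Benign`, `MoD`, `HiD`, `SCC`.
#' @export
oral_lesion_distribution <- function() {
  path <- system.file("extdata", "lesion_distribution.csv",
                      package = "oralaf", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Binary class counts of the clinical cohort
#'
#' Maps the histopathology counts of [oral_lesion_distribution()] through
#' the binary label rule (MoD, HiD and SCC positive; Benign negative).
#'
#' @return Named integer vector `c(positive, benign, total)`.
#' @export
lesion_label_counts <- function() {
  d <- oral_lesion_distribution()
  pos <- sum(d[, POSITIVE_LEVELS])
  ben <- sum(d[, "Benign"])
  c(positive = pos, benign = ben, total = pos + ben)
}
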