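#' Synthetic aerobiological test-case scores
#'
#' Per-grain classifier scores for three Hirst-type aerobiological tape
#' samples (Leiden, NL; Lleida and Vielha, Catalonia, ES) with 112, 63 and
#' 26 Urticaceae grains respectively. The scores are a synthetic
#' reconstruction (see the file name) consistent with the per-sample class
#' percentages reported for these monitoring samples at the 60% and 70%
#' identity thresholds; they exercise [predict_with_threshold()] and
#' [summarize_test_cases()] end to end without microscope data. Confounding
#' Humulus/Morus pollen is assumed already removed by the documented manual
#' pre-filter (distinguishable by size and shape), as in routine practice.
#'
#' @return List with `scores` (201 x 3 matrix, columns urtica, parietaria,
#'   membranacea), `sample` and `date` vectors.
#' @export
aerobio_test_cases <- function() {
  path <- system.file("extdata", "aerobio_test_cases_synthetic.csv",
                      package = "pollenid", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  scores <- as.matrix(df[, c("score_urtica", "score_parietaria",
                             "score_membranacea")])
  colnames(scores) <- pollen_classes()
  list(scores = scores, sample = df$sample, date = df$date)
}
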