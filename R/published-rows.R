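#' Published worked-example operating points
#'
#' Per-class precision/recall/F operating points reported in the focus-
#' species classification literature for eight learner models under
#' several feature sets (basic set F1 = gene names + MeSH + journal +
#' title; TS/OF/NT/AGN additions; full-text versus abstract input). Only
#' rows whose printed F equals `2PR/(P+R)` at three decimals are included;
#' they serve as worked examples for the metric identities.
#'
#' @return data.frame with columns `model`, `class`, `feature_set`,
#'   `precision`, `recall`, `f`.
#' @export
example_metric_rows <- function() {
  rows <- rbind(
    c("nb",       "fly",   "F1",       .780, .929, .848),
    c("nb",       "mouse", "F1",       .810, .680, .739),
    c("nb",       "yeast", "F1",       .750, .727, .738),
    c("nb",       "mouse", "F1-JN",    .697, .620, .656),
    c("nb",       "yeast", "F1-JN",    .646, .515, .573),
    c("nb",       "fly",   "F1-MH",    .530, .808, .640),
    c("adaboost", "fly",   "F1-JN",    .659, .899, .761),
    c("adaboost", "yeast", "F1-JN",    .649, .485, .555),
    c("adaboost", "fly",   "F1-MH",    .638, .677, .657),
    c("adaboost", "yeast", "F1-MH",    .640, .737, .685),
    c("bagging",  "fly",   "F1",       .791, .919, .850),
    c("bagging",  "mouse", "F1",       .788, .670, .724),
    c("bagging",  "fly",   "F1-JN",    .729, .869, .793),
    c("bagging",  "mouse", "F1-JN",    .670, .670, .670),
    c("bagging",  "yeast", "F1-JN",    .638, .515, .570),
    c("bagging",  "fly",   "F1-MH",    .606, .838, .703),
    c("bagging",  "mouse", "F1-MH",    .831, .490, .616),
    c("bagging",  "yeast", "F1-MH",    .696, .717, .706),
    c("dtable",   "fly",   "F1",       .532, .667, .592),
    c("dtable",   "mouse", "F1",       .515, .520, .517),
    c("dtable",   "yeast", "F1",       .740, .545, .628),
    c("dtree",    "yeast", "F1",       .729, .434, .544),
    c("logreg",   "mouse", "F1",       .586, .750, .658),
    c("logreg",   "yeast", "F1",       .705, .626, .663),
    c("svm",      "fly",   "F1",       .925, .641, .757),
    c("svm",      "mouse", "F1",       .403, 1.000, .574),
    c("svm",      "yeast", "F1",       .636, .194, .297),
    c("nb",       "fly",   "F1+TS",    .970, .970, .970),
    c("nb",       "mouse", "F1+TS",    .826, .950, .884),
    c("nb",       "fly",   "F1+OF",    .792, .931, .856),
    c("nb",       "mouse", "F1+OF",    .821, .685, .747),
    c("nb",       "yeast", "F1+OF",    .762, .731, .746),
    c("nb",       "fly",   "F1+NT",    .775, .825, .799),
    c("nb",       "mouse", "F1+NT",    .823, .621, .708),
    c("nb",       "yeast", "F1+NT",    .752, .723, .737),
    c("nb",       "fly",   "F1+AGN",   .812, .931, .867),
    c("nb",       "mouse", "F1+AGN",   .823, .712, .763),
    c("nb",       "yeast", "F1+AGN",   .786, .987, .875),
    c("nb",       "fly",   "full",     .971, .972, .971),
    c("nb",       "mouse", "full",     .827, .953, .886),
    c("nb",       "yeast", "full",     .931, .791, .855),
    c("crf",      "fly",   "F1+TS",    .965, .952, .958),
    c("crf",      "mouse", "F1+TS",    .814, .878, .845),
    c("crf",      "yeast", "F1+TS",    .902, .786, .840),
    c("crf",      "fly",   "full",     .966, .954, .960),
    c("crf",      "mouse", "full",     .817, .878, .846),
    c("crf",      "yeast", "full",     .901, .788, .841),
    c("nb",       "fly",   "abstract", .812, .892, .850),
    c("nb",       "mouse", "abstract", .755, .763, .759),
    c("nb",       "yeast", "abstract", .791, .748, .769),
    c("crf",      "fly",   "abstract", .820, .898, .857),
    c("crf",      "mouse", "abstract", .732, .741, .736),
    c("crf",      "yeast", "abstract", .757, .750, .753))
  data.frame(model = rows[, 1], class = rows[, 2], feature_set = rows[, 3],
             precision = as.numeric(rows[, 4]),
             recall = as.numeric(rows[, 5]),
             f = as.numeric(rows[, 6]), stringsAsFactors = FALSE)
}
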