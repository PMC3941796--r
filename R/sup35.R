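# Published classification results on overlapping fragments of the yeast
# prion sup35: 12 experimentally amyloidogenic and 31 non-amyloidogenic
# fragments with the scores and calls reported for them. A few scores were
# printed with comma decimal separators; raw_score keeps the original
# spelling, printed_score the parsed value.

#' Prion sup35 fragment test fixture
#'
#' The bundled independent test set: 43 overlapping fragments of the yeast
#' prion protein sup35 (12 labeled amyloidogenic, 31 not), together with
#' the published per-fragment window score `w_s` and the published +/- call
#' for each. Fragment ids are the original 1-based inclusive residue
#' ranges. Applying any decision threshold strictly between 0.12 and 0.13
#' to `printed_score` reproduces `printed_call` for all 43 fragments.
#'
#' @return Data frame with columns `id`, `sequence`, `label` (the
#'   experimental ground truth), `source`, `printed_call` (`"+"`/`"-"`),
#'   `printed_score` (numeric `w_s`), `raw_score` (score as originally
#'   printed, including comma-decimal variants).
#' @examples
#' s35 <- sup35_fixture()
#' table(s35$label)
#' confusion(s35$label, s35$printed_score > 0.125)
#' @export
sup35_fixture <- function() {
  pos <- c(
    "7-17",    "GNNQQNYQQY", "+", "0.34",
    "16-26",   "YSQNGNQQQG", "-", "0.08",
    "28-38",   "RYQGYQAYNA", "+", "0.21",
    "43-53",   "GGYYQNYQGY", "+", "0.53",
    "46-56",   "YQNYQGYSGY", "+", "0.53",
    "52-62",   "YSGYQQGGYQ", "+", "0.16",
    "55-65",   "YQQGGYQQYN", "+", "0.13",
    "94-104",  "PQGGRGNYKN", "-", "0.09",
    "103-113", "NFNYNNNLQG", "+", "0.22",
    "106-116", "YNNNLQGYQA", "+", "0.17",
    "109-119", "NLQGYQAGFQ", "+", "0.17",
    "127-137", "NDFQKQQKQA", "-", "0.11")
  neg <- c(
    "67-76",   "AGYQQQYNPQ", "+", "0.17",
    "70-79",   "QQQYNPQGGY", "-", "0.08",
    "73-82",   "YNPQGGYQQY", "-", "0.06",
    "76-85",   "QGGYQQYNPQ", "+", "0.13",
    "79-88",   "YQQYNPQGGY", "+", "0.13",
    "82-91",   "YNPQGGYQQQ", "-", "0.03",
    "139-148", "KPKKTLKLVS", "-", "0.09",
    "142-151", "KTLKLVSSSG", "-", "0.09",
    "145-154", "KLVSSSGIKL", "-", "0.12",
    "148-157", "SSSGIKLANA", "-", "0,12",
    "151-160", "GIKLANATKK", "-", "0,07",
    "154-163", "LANATKKVGT", "-", "0,07",
    "157-166", "ATKKVGTKPA", "-", "0,03",
    "160-169", "KVGTKPAESD", "-", "0,03",
    "163-172", "TKPAESDKKE", "-", "0,03",
    "166-175", "AESDKKEEEK", "-", "0.03",
    "169-178", "DKKEEEKSAE", "-", "0.03",
    "172-181", "EEEKSAETKE", "-", "0.03",
    "175-184", "KSAETKEPTK", "-", "0.06",
    "178-187", "ETKEPTKEPT", "-", "0.06",
    "181-190", "EPTKEPTKVE", "-", "0.06",
    "184-193", "KEPTKVEEPV", "-", "0.09",
    "187-196", "TKVEEPVKKE", "-", "0.09",
    "190-199", "EEPVKKEEKP", "-", "0.03",
    "193-202", "VKKEEKPVQT", "-", "0.03",
    "196-205", "EEKPVQTEEK", "-", "0.03",
    "199-208", "PVQTEEKTEE", "-", "0.11",
    "202-211", "TEEKTEEKSE", "-", "0.11",
    "205-214", "KTEEKSELPK", "-", "0.08",
    "208-217", "EKSELPKVED", "-", "0.08",
    "211-220", "ELPKVEDLKI", "-", "0.11")
  m <- matrix(c(pos, neg), ncol = 4L, byrow = TRUE)
  data.frame(
    id = m[, 1L],
    sequence = m[, 2L],
    label = rep(c("positive", "negative"),
                c(length(pos) / 4L, length(neg) / 4L)),
    source = "sup35",
    printed_call = m[, 3L],
    printed_score = as.numeric(sub(",", ".", m[, 4L], fixed = TRUE)),
    raw_score = m[, 4L],
    stringsAsFactors = FALSE)
}
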