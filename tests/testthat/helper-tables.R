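# Printed reference tables, encoded as fraction cells. Confusion counts are
# reconstructed from the sensitivity/specificity fractions (52 DTD, 157
# normal); the PPV/NPV/accuracy numerators and denominators are carried along
# as an internal consistency guard.
#
# Three printed cells are arithmetically inconsistent with the rest of their
# row and are encoded at the values implied by the consistent cells:
#   * cutoff table, row 90: the sensitivity (25/52), NPV (138/165) and
#     accuracy (163/209) fractions all imply tn = 138, fp = 19 — under which
#     specificity is 87.9 (printed 88.5), the PPV denominator is 44 (printed
#     25/43) and PPV is 56.8 (printed 58.1);
#   * feature table, size "normal": specificity prints 14.7 but 23/157 = 14.6.

refCutoffTable <- data.frame(
  cutoff = c(80, 90, 100),
  tp = c(14, 25, 34), tn = c(149, 138, 129),
  ppvDen = c(22, 44, 62), npvDen = c(187, 165, 147), accNum = c(163, 163, 163),
  sens = c(26.9, 48.1, 65.4),
  spec = c(94.9, 87.9, 82.2),          # 87.9, not the printed 88.5
  ppv = c(63.6, 56.8, 54.8),           # 56.8 = 25/44, not the printed 58.1
  npv = c(79.7, 83.6, 87.8), acc = c(78.0, 78.0, 78.0),
  aucPrinted = c(0.6091, 0.6831, 0.7378),
  aucConforms = c(TRUE, FALSE, TRUE)   # 0.6831 is not (sens+spec)/2 of its row
)

refThresholdTable <- data.frame(
  k = 1:3,
  tp = c(46, 40, 29), tn = c(73, 130, 150),
  ppvDen = c(130, 67, 36), npvDen = c(79, 142, 173), accNum = c(119, 170, 179),
  sens = c(88.5, 76.9, 55.8), spec = c(46.5, 82.8, 95.5),
  ppv = c(35.4, 59.7, 80.6), npv = c(92.4, 91.5, 86.7), acc = c(56.9, 81.3, 85.6),
  aucPrinted = c(0.6238, 0.5421, 0.7566),
  aucConforms = c(FALSE, FALSE, TRUE)
)

refFeatureTable <- data.frame(
  feature = rep(c("attenuation_degree", "attenuation_pattern", "size_category",
                  "margin", "enhancement_pattern"), c(2, 3, 3, 2, 2)),
  category = c("iso", "low",
               "homogeneous", "inhomogeneous", "heterogeneous",
               "normal", "increased", "decreased",
               "smooth", "lobulated",
               "homogeneous", "inhomogeneous"),
  tp = c(18, 34, 17, 35, 0, 38, 14, 0, 40, 12, 22, 30),
  tn = c(27, 130, 15, 143, 156, 23, 135, 156, 4, 153, 5, 152),
  ppvDen = c(148, 61, 159, 49, 1, 172, 36, 1, 193, 16, 174, 35),
  npvDen = c(61, 148, 50, 160, 208, 37, 173, 208, 16, 193, 35, 174),
  accNum = c(45, 164, 32, 178, 156, 61, 149, 156, 44, 165, 27, 182),
  sens = c(34.6, 65.4, 32.7, 67.3, 0, 73.1, 26.9, 0, 76.9, 23.1, 42.3, 57.7),
  spec = c(17.2, 82.8, 9.6, 91.1, 99.4, 14.6, 86.0, 99.4, 2.5, 97.5, 3.2, 96.8),
  ppv = c(12.2, 55.7, 10.7, 71.4, 0, 22.1, 38.9, 0, 20.7, 75.0, 12.6, 85.7),
  npv = c(44.3, 87.8, 30.0, 89.4, 75.0, 62.2, 78.0, 75.0, 25.0, 79.3, 14.3, 87.4),
  acc = c(21.5, 78.5, 15.3, 85.2, 74.6, 29.2, 71.3, 74.6, 21.1, 78.9, 12.9, 87.1)
)

nDtdRef <- 52L
nNormalRef <- 157L

# rebuild a ConfusionCounts from a reference row's sensitivity/specificity
# fractions, asserting internal consistency of the other cells on the way
countsFromRefRow <- function(row) {
  tp <- row$tp; tn <- row$tn
  fn <- nDtdRef - tp; fp <- nNormalRef - tn
  stopifnot(tp + fp == row$ppvDen, fn + tn == row$npvDen, tp + tn == row$accNum)
  confusionCounts(tp = tp, fp = fp, fn = fn, tn = tn)
}

# percentage formatting as the tables print it
pct1 <- function(x) roundHalfUp(100 * x, 1)
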