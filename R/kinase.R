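#' Construct a KinasePSSM
#'
#' @param kinase Kinase name.
#' @param scores Numeric matrix of positive preference odds, rows = the 20
#'   residues (any order; reordered to [AA20]), columns = signed offsets over
#'   a contiguous range including +2.
#' @return A validated [KinasePSSM-class].
#' @export
newKinasePSSM <- function(kinase, scores) {
  scores <- scores[AA20, , drop = FALSE]
  new("KinasePSSM", kinase = kinase, scores = scores)
}

#' Read kinase PSSMs from a long-format TSV
#'
#' Expects tab-separated columns `kinase`, `position`, `residue`, `score`
#' (peptide-library derived preference odds, strictly positive). Returns one
#' [KinasePSSM-class] per kinase.
#'
#' @param path TSV path.
#' @return Named list of [KinasePSSM-class].
#' @export
readKinasePSSMs <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("kinase", "position", "residue", "score")
  if (!all(need %in% names(x)))
    stop("PSSM table must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(x, x$kinase), function(d) {
    pos <- sort(unique(as.integer(d$position)))
    m <- matrix(NA_real_, 20L, length(pos),
                dimnames = list(AA20, as.character(pos)))
    m[cbind(match(d$residue, AA20), match(as.integer(d$position), pos))] <-
      d$score
    if (anyNA(m)) stop("incomplete PSSM for kinase ", d$kinase[1L])
    newKinasePSSM(d$kinase[1L], m)
  })
  out[sort(names(out))]
}

#' Per-position glutamate preference of one kinase
#'
#' Transforms a kinase's raw peptide-library scores into a normalized
#' glutamate-preference profile in [0, 1], one value per position:
#'
#' * `rank_quantile` (default): the fraction of the 20 residues at that
#'   position scoring below E, ties counted half — robust to the unknown
#'   scaling of published library matrices. A uniform column gives 0.475
#'   (9.5/20); E dominant over all 19 others gives 0.95.
#' * `row_max`: E's score divided by the column maximum.
#' * `log_odds_z`: the standard-normal CDF of E's z-score among the
#'   log-scores of the column (bounded, scale-invariant).
#'
#' @param pssm A [KinasePSSM-class].
#' @param normalization One of `"rank_quantile"`, `"row_max"`, `"log_odds_z"`.
#' @return Named numeric vector over the PSSM's offsets, values in [0, 1].
#' @export
gluPreference <- function(pssm,
                          normalization = c("rank_quantile", "row_max",
                                            "log_odds_z")) {
  stopifnot(is(pssm, "KinasePSSM"))
  normalization <- match.arg(normalization)
  sc <- pssm@scores
  if (!"2" %in% colnames(sc)) stop("PSSM is missing the +2 position")
  e <- sc["E", ]
  vals <- switch(normalization,
    rank_quantile = vapply(seq_len(ncol(sc)), function(j) {
      others <- sc[setdiff(AA20, "E"), j]
      (sum(others < e[j]) + 0.5 * sum(others == e[j])) / 20
    }, numeric(1)),
    row_max = e / apply(sc, 2L, max),
    log_odds_z = vapply(seq_len(ncol(sc)), function(j) {
      lg <- log(sc[, j])
      s <- stats::sd(lg)
      if (s == 0) return(0.5)  # uniform column: no preference
      pnorm((lg["E"] - mean(lg)) / s)
    }, numeric(1)))
  setNames(vals, colnames(sc))
}

#' Build a PreferenceMatrix over a kinase panel
#'
#' Applies [gluPreference()] to each PSSM; kinases must share an offset
#' range.
#'
#' @param pssms List of [KinasePSSM-class].
#' @param normalization Passed to [gluPreference()].
#' @return A [PreferenceMatrix-class] (rows = kinases, columns = offsets).
#' @export
preferenceMatrix <- function(pssms, normalization = "rank_quantile") {
  if (length(pssms) == 0L) stop("empty kinase panel")
  rows <- lapply(pssms, gluPreference, normalization = normalization)
  offs <- names(rows[[1L]])
  if (!all(vapply(rows, function(r) identical(names(r), offs), logical(1))))
    stop("kinases must share one offset range")
  values <- do.call(rbind, rows)
  rownames(values) <- unname(vapply(pssms, function(p) p@kinase,
                                    character(1)))
  new("PreferenceMatrix", values = values, normalization = normalization)
}

#' Flag kinases with a dominant +2 glutamate preference
#'
#' A kinase is a +2 specialist when its +2 preference value strictly exceeds
#' every other position's value for that kinase by at least `margin`, and
#' strictly exceeds the cross-kinase median +2 value by at least `margin`.
#' With `margin = 0`, exact ties never qualify (strict inequality).
#'
#' @param matrix A [PreferenceMatrix-class].
#' @param margin Required separation on the [0, 1] scale, default 0.2.
#' @return Character vector of flagged kinase names (possibly empty).
#' @export
flagPlus2Specialists <- function(matrix, margin = 0.2) {
  stopifnot(is(matrix, "PreferenceMatrix"))
  v <- matrix@values
  if (!"2" %in% colnames(v)) stop("matrix is missing the +2 position")
  plus2 <- v[, "2"]
  rest <- v[, setdiff(colnames(v), "2"), drop = FALSE]
  med <- median(plus2)
  ok <- plus2 > apply(rest, 1L, max) + margin & plus2 > med + margin
  rownames(v)[ok]
}

#' Write a PreferenceMatrix to TSV
#'
#' @param matrix A [PreferenceMatrix-class].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writePreferenceMatrix <- function(matrix, path) {
  v <- matrix@values[order(rownames(matrix@values)), , drop = FALSE]
  df <- data.frame(kinase = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
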