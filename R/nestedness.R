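# Nestedness temperature, the row/column-fill (Ce) null ensemble, and
# relative nestedness.

#' Matrix temperature
#'
#' Atmar-Patterson matrix temperature of a binary matrix: rows and columns
#' are packed by marginal totals, a fill-respecting isocline of perfect
#' nestedness is constructed, and each unexpected cell (a hole above the
#' isocline or a presence below it) is scored by its squared scaled distance
#' along the cell's diagonal, normalised so the theoretical maximum maps to
#' 100.  T = 0 is a perfectly nested matrix; larger T is more disordered.
#' The statistic itself is computed by [vegan::nestedtemp()], the standard
#' implementation of this geometry; this wrapper fixes the package's
#' conventions for degenerate input.
#'
#' The consumer-by-resource matrix is scored as a bipartite incidence matrix
#' (rows and columns treated as separate modes), matching how predator-prey
#' matrices are conventionally fed to nestedness calculators.
#'
#' A matrix with no absences or no presences is perfectly ordered by
#' convention: T = 0, with a warning.  All-zero rows and columns are
#' retained.
#'
#' @param x a binary matrix or a [FoodWeb-class].
#' @return matrix temperature in \[0, 100\].
#' @export
setMethod("matrixTemperature", "matrix", function(x) {
  if (length(x) == 0L) stop("empty matrix")
  if (!all(x %in% c(0, 1))) stop("matrix must be binary")
  fill <- mean(x)
  if (fill == 0 || fill == 1) {
    warning("matrix is completely ", if (fill == 0) "empty" else "filled",
            "; temperature is 0 by convention")
    return(0)
  }
  # nestedtemp's packing refinement consumes RNG state; pin it so the
  # statistic is a deterministic function of the matrix
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(1L)
  unname(vegan::nestedtemp(x)$statistic)
})

#' @describeIn matrixTemperature method for FoodWeb
#' @export
setMethod("matrixTemperature", "FoodWeb", function(x)
  matrixTemperature(x@adj))

#' Ce null ensemble
#'
#' Null matrices in which cell (i, j) is occupied independently with
#' probability `p_ij = (f_row_i + f_col_j) / 2`, the mean of the observed
#' fill of row i and of column j.  This preserves the observed fill pattern
#' in expectation while randomising its arrangement.
#'
#' @param web a [FoodWeb-class] or binary matrix.
#' @param replicates ensemble size (at least 100 recommended for p-values).
#' @param seed integer RNG seed; the ensemble is reproducible from it.
#' @return list of `replicates` binary matrices.
#' @export
ceNullEnsemble <- function(web, replicates = 1000L, seed = 1L) {
  a <- if (is(web, "FoodWeb")) web@adj else web
  if (sum(a) == 0L) stop("cannot build a null ensemble for an empty web")
  if (replicates < 1L) stop("replicates must be positive")
  p <- (matrix(rowMeans(a), nrow(a), ncol(a)) +
        matrix(colMeans(a), nrow(a), ncol(a), byrow = TRUE)) / 2
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  lapply(seq_len(replicates), function(i)
    matrix(stats::rbinom(length(p), 1L, p), nrow(a), ncol(a)))
}

#' Nestedness analysis with a Ce null model
#'
#' Computes the observed temperature T and nestedness N = (100 - T) / 100,
#' scores a Ce null ensemble, and reports the one-sided significance (how
#' often a null matrix is at least as nested, i.e. has temperature less than
#' or equal to the observed one, with the +1 pseudo-count convention) and the
#' relative nestedness n* = (N - Nbar) / Nbar, where Nbar is the null mean.
#'
#' @param web a [FoodWeb-class].
#' @param replicates null ensemble size.
#' @param seed integer RNG seed.
#' @param label web label stored in the result.
#' @return a [NestednessResult-class].
#' @examples
#' fw <- generateWeb(S = 30, lambda = 1.5, seed = 7)
#' nestednessAnalysis(fw, replicates = 100, seed = 7)
#' @export
setMethod("nestednessAnalysis", "FoodWeb",
          function(web, replicates = 1000L, seed = 1L, label = "web") {
  if (replicates < 100L)
    warning("fewer than 100 null replicates gives coarse p-values")
  tObs <- matrixTemperature(web)
  nulls <- ceNullEnsemble(web, replicates = replicates, seed = seed)
  tNull <- vapply(nulls, function(m) suppressWarnings(matrixTemperature(m)),
                  numeric(1))
  nObs <- (100 - tObs) / 100
  nNull <- (100 - tNull) / 100
  nullMean <- mean(nNull)
  new("NestednessResult", web = label, temperature = tObs,
      nestedness = nObs, nullMean = nullMean, nullSd = stats::sd(nNull),
      pValue = (1 + sum(tNull <= tObs)) / (replicates + 1),
      nStar = (nObs - nullMean) / nullMean,
      replicates = as.integer(replicates), seed = as.integer(seed))
})

#' Tidy one-row summary of a NestednessResult
#' @param x a [NestednessResult-class]
#' @return one-row data.frame mirroring the result slots.
#' @export
nestednessTable <- function(x) {
  stopifnot(is(x, "NestednessResult"))
  data.frame(web = x@web, T = x@temperature, N = x@nestedness,
             null_mean = x@nullMean, null_sd = x@nullSd, p_value = x@pValue,
             n_star = x@nStar, replicates = x@replicates, seed = x@seed)
}
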