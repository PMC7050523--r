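#' Read tidy plate-reader growth curves
#'
#' @param path TSV with columns `strain`, `plate`, `concentration`
#'   (mg/L), `time_h`, `od`.
#' @return data.frame, validated (times strictly increasing within each
#'   strain/plate/concentration series, OD non-negative, >= 2 points per
#'   series).
#' @export
readGrowthCurves <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("strain", "plate", "concentration", "time_h", "od")
  if (!all(need %in% names(df)))
    stop("growth TSV must contain columns: ", paste(need, collapse = ", "))
  if (any(df$od < 0)) stop("optical densities must be non-negative")
  key <- interaction(df$strain, df$plate, df$concentration, drop = TRUE)
  for (k in levels(key)) {
    t <- df$time_h[key == k]
    if (length(t) < 2L) stop("growth series ", k, " has fewer than 2 points")
    if (any(diff(t) <= 0)) stop("times not strictly increasing in series ", k)
  }
  df
}

#' Incremental area under a growth curve
#'
#' Trapezoidal integral of the optical density above the curve's own
#' first reading, \code{max(0, od(t) - od(t0))}, in AU.h. Self-baselining
#' to the first reading of the same well removes inoculum differences;
#' dips below baseline contribute zero area rather than negative.
#'
#' @param times strictly increasing times in hours (>= 2 points).
#' @param od optical densities, same length.
#' @return iAUC in AU.h, >= 0.
#' @examples
#' iauc(c(0, 1, 2), c(0.1, 0.3, 0.5))  # 0.4
#' @export
iauc <- function(times, od) {
  if (length(times) < 2L) stop("need at least 2 time points")
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  pracma::trapz(times, pmax(0, od - od[1L]))
}

#' Fitness ratios from growth under drug exposure
#'
#' For every strain/plate, the fitness ratio is the iAUC at the treated
#' concentration divided by the mean iAUC at the reference
#' concentrations, clamped to [0, 1] (a value of 1 means growth under
#' treatment matches drug-free growth; 0 means no incremental growth).
#' The defaults reproduce the triclosan design: treated 0.125 mg/L,
#' references 0 and 0.015 mg/L.
#'
#' @param curves data.frame as from [readGrowthCurves()].
#' @param treated treated concentration (mg/L).
#' @param refs reference concentrations averaged in the denominator.
#' @return data.frame per strain/plate: `strain`, `plate`,
#'   `iauc_treated`, `iauc_ref`, `ratio`, `clamped`, `undefined`
#'   (TRUE when the reference iAUC is 0, in which case `ratio` is NA).
#' @export
fitnessRatios <- function(curves, treated = 0.125, refs = c(0, 0.015)) {
  pairs <- unique(curves[, c("strain", "plate")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- curves[curves$strain == pairs$strain[i] &
                    curves$plate == pairs$plate[i], , drop = FALSE]
    one <- function(conc) {
      s <- sub[sub$concentration == conc, , drop = FALSE]
      if (!nrow(s))
        stop("strain ", pairs$strain[i], " plate ", pairs$plate[i],
             " lacks concentration ", conc)
      s <- s[order(s$time_h), ]
      iauc(s$time_h, s$od)
    }
    it <- one(treated)
    ir <- mean(vapply(refs, one, numeric(1)))
    undefined <- ir == 0
    raw <- if (undefined) NA_real_ else it / ir
    data.frame(strain = pairs$strain[i], plate = pairs$plate[i],
               iauc_treated = it, iauc_ref = ir,
               ratio = if (undefined) NA_real_ else min(max(raw, 0), 1),
               clamped = !undefined && (raw > 1 || raw < 0),
               undefined = undefined)
  })
  do.call(rbind, rows)
}

#' Zero-avoidance shift for a set of fitness ratios
#'
#' Adds the smallest nonzero ratio in the data set to every value, so all
#' shifted ratios are strictly positive (ready for beta-family modelling
#' downstream).
#'
#' @param ratios numeric vector of clamped fitness ratios in [0, 1].
#' @return shifted ratios, all > 0.
#' @examples
#' shiftRatios(c(0, 0.2, 0.5))  # 0.2 0.4 0.7
#' @export
shiftRatios <- function(ratios) {
  nz <- ratios[!is.na(ratios) & ratios > 0]
  if (!length(nz)) stop("no nonzero ratios; shift undefined")
  ratios + min(nz)
}

#' Summarize mutant fitness against the parent strain
#'
#' Descriptive per-strain summary: mean fitness ratio, difference versus
#' the parent's mean, and a flag for differences exceeding 20% of the
#' parent mean.
#'
#' @param ratios data.frame from [fitnessRatios()] (column `ratio`).
#' @param parent parent strain name; must be present.
#' @return data.frame per strain: `strain`, `n`, `mean_ratio`,
#'   `diff_vs_parent`, `exceeds_20pct`.
#' @export
compareToParent <- function(ratios, parent) {
  if (!parent %in% ratios$strain)
    stop("parent strain '", parent, "' not present")
  ok <- !is.na(ratios$ratio)
  means <- tapply(ratios$ratio[ok], ratios$strain[ok], mean)
  ns <- tapply(ratios$ratio[ok], ratios$strain[ok], length)
  pm <- means[[parent]]
  data.frame(strain = names(means), n = as.integer(ns),
             mean_ratio = as.numeric(means),
             diff_vs_parent = as.numeric(means) - pm,
             exceeds_20pct = abs(as.numeric(means) - pm) > 0.2 * pm,
             row.names = NULL)
}
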