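#' Free ammonia concentration from TAN, pH and temperature
#'
#' Computes the un-ionised (free) ammonia fraction of total ammonia nitrogen
#' (TAN), the inhibitory species for methanogens in anaerobic digesters. The
#' equilibrium between NH4+ and NH3 shifts towards free ammonia with rising pH
#' and temperature:
#'
#' \deqn{FA = 1.214 \cdot TAN \cdot
#'   \left(1 + \frac{10^{-pH}}{10^{-(0.09018 + 2729.92/T)}}\right)^{-1}}
#'
#' with \eqn{T} in Kelvin. Temperature is accepted in degrees Celsius and
#' converted internally (\code{T = temperature_C + 273.15}), since reactor
#' operating temperatures are conventionally reported in Celsius.
#'
#' @param TAN Total ammonia nitrogen, mg-N/L. Must be non-negative.
#' @param pH Reactor pH, strictly inside (0, 14).
#' @param temperature_C Temperature in degrees Celsius.
#' @return Free ammonia in mg-N/L, same length as the inputs (vectorised,
#'   recycled to a common length).
#' @examples
#' free_ammonia(TAN = 93, pH = 7.5, temperature_C = 35)
#' free_ammonia(TAN = 1217, pH = 7.0, temperature_C = 52)
#' @export
free_ammonia <- function(TAN, pH, temperature_C) {
  n <- max(length(TAN), length(pH), length(temperature_C))
  TAN <- rep_len(TAN, n)
  pH <- rep_len(pH, n)
  temperature_C <- rep_len(temperature_C, n)
  if (any(!is.finite(TAN)) || any(!is.finite(pH)) || any(!is.finite(temperature_C)))
    stop("free_ammonia: all inputs must be finite", call. = FALSE)
  if (any(TAN < 0))
    stop("free_ammonia: TAN must be non-negative (mg-N/L)", call. = FALSE)
  if (any(pH <= 0 | pH >= 14))
    stop("free_ammonia: pH must lie strictly between 0 and 14", call. = FALSE)
  T_K <- temperature_C + 273.15
  if (any(T_K <= 0))
    stop("free_ammonia: temperature below absolute zero", call. = FALSE)
  pKa_like <- 0.09018 + 2729.92 / T_K
  1.214 * TAN / (1 + 10^(-pH) / 10^(-pKa_like))
}

#' Hydrolysis efficiency from COD balances
#'
#' Fraction of removed total COD that passed through hydrolysis, estimated
#' from the soluble COD balance plus methane produced (expressed as COD):
#' \deqn{(sCOD_{eff} - sCOD_{inf} + COD_{CH4}) / (tCOD_{inf} - tCOD_{eff})}
#'
#' @param sCOD_eff,sCOD_inf Effluent / influent soluble COD, g/L.
#' @param COD_CH4 Methane produced per volume fed, expressed as COD, g/L.
#' @param tCOD_inf,tCOD_eff Influent / effluent total COD, g/L.
#' @return Hydrolysis efficiency as a fraction (not percent). Vectorised.
#' @seealso [methanogenesis_efficiency()], [d_efficiency()]
#' @export
hydrolysis_efficiency <- function(sCOD_eff, sCOD_inf, COD_CH4, tCOD_inf, tCOD_eff) {
  .check_cod(sCOD_eff, sCOD_inf, COD_CH4, tCOD_inf, tCOD_eff)
  (sCOD_eff - sCOD_inf + COD_CH4) / (tCOD_inf - tCOD_eff)
}

#' Methanogenesis efficiency from COD balances
#'
#' Fraction of removed total COD recovered as methane:
#' \deqn{COD_{CH4} / (tCOD_{inf} - tCOD_{eff})}
#'
#' Always bounded above by [hydrolysis_efficiency()] whenever effluent soluble
#' COD is at least influent soluble COD.
#'
#' @inheritParams hydrolysis_efficiency
#' @return Methanogenesis efficiency as a fraction. Vectorised.
#' @export
methanogenesis_efficiency <- function(COD_CH4, tCOD_inf, tCOD_eff) {
  .check_cod(COD_CH4, tCOD_inf, tCOD_eff)
  COD_CH4 / (tCOD_inf - tCOD_eff)
}

.check_cod <- function(..., tol = 0) {
  args <- list(...)
  nm <- vapply(substitute(list(...))[-1], deparse, character(1))
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]])))
      stop("non-finite COD measurement in ", nm[i], call. = FALSE)
    if (any(args[[i]] < 0))
      stop("negative COD measurement in ", nm[i], call. = FALSE)
  }
  a <- list(...)
  tinf <- a[[length(a) - 1L]]
  teff <- a[[length(a)]]
  if (any(tinf <= teff))
    stop("undefined efficiency: tCOD_inf must exceed tCOD_eff ",
         "(no net COD removal)", call. = FALSE)
  invisible(TRUE)
}

#' First-order hydrolysis rate constant from a batch degradation series
#'
#' Fits the first-order hydrolysis constant K_H (1/day) from a batch time
#' series of soluble COD and cumulative methane (as COD). Under first-order
#' kinetics the degradable particulate pool S decays as
#' \eqn{S_t = S_0 e^{-K_H t}}, and hydrolysed COD accumulates in the
#' soluble + methane pool, so
#' \deqn{K_H = \frac{1}{\Delta t}\,\ln\!\left(
#'   \frac{COD_{CH4,end} + sCOD_{end} - sCOD_0}
#'        {(COD_{CH4,end} + sCOD_{end}) - (COD_{CH4,t} + sCOD_t)}\right)}
#'
#' where the end point defines the ultimately hydrolysable COD.
#'
#' @param times Sampling times in days, strictly increasing, length >= 2.
#' @param sCOD_t Soluble COD at each time, g/L.
#' @param COD_CH4_t Cumulative methane as COD at each time, g/L,
#'   non-decreasing.
#' @param t_index Index of the interior time point used for the single-point
#'   estimate. Defaults to the midpoint sample of the series. Ignored when
#'   \code{method = "lsq"}.
#' @param method `"point"` (default) evaluates the closed form at
#'   \code{t_index}; `"lsq"` is an extension that least-squares fits
#'   \eqn{\log} of the remaining pool over all interior time points.
#' @return K_H in 1/day.
#' @examples
#' # exact first-order decay towards an ultimate pool of 100 g/L
#' hydrolysis_rate_constant(times = c(0, 5, 30),
#'                          sCOD_t = c(0, 13.212, 20),
#'                          COD_CH4_t = c(0, 50, 80), t_index = 2)
#' @export
hydrolysis_rate_constant <- function(times, sCOD_t, COD_CH4_t,
                                     t_index = NULL,
                                     method = c("point", "lsq")) {
  method <- match.arg(method)
  if (length(times) < 2L)
    stop("need at least two time points", call. = FALSE)
  if (length(sCOD_t) != length(times) || length(COD_CH4_t) != length(times))
    stop("times, sCOD_t and COD_CH4_t must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(diff(COD_CH4_t) < 0))
    stop("cumulative COD_CH4_t must be non-decreasing", call. = FALSE)
  n <- length(times)
  end_pool <- COD_CH4_t[n] + sCOD_t[n]
  num <- end_pool - sCOD_t[1L]
  remaining <- end_pool - (COD_CH4_t + sCOD_t)
  if (method == "lsq") {
    idx <- 2:(n - 1L)
    idx <- idx[remaining[idx] > 0]
    if (length(idx) < 1L)
      stop("degradation complete at every interior point; cannot fit",
           call. = FALSE)
    dt <- times[idx] - times[1L]
    y <- log(num / remaining[idx])
    # regression through the origin of ln-ratio on elapsed time
    return(sum(dt * y) / sum(dt * dt))
  }
  if (is.null(t_index)) t_index <- max(2L, ceiling(n / 2))
  if (t_index < 2L || t_index > n)
    stop("t_index out of range", call. = FALSE)
  dt <- times[t_index] - times[1L]
  if (dt == 0) stop("zero elapsed time", call. = FALSE)
  den <- remaining[t_index]
  if (den <= 0)
    stop("degradation complete at t_index: log argument not positive",
         call. = FALSE)
  if (num <= 0)
    stop("no hydrolysable COD: numerator not positive", call. = FALSE)
  log(num / den) / dt
}

#' Relative differential efficiency between hydrolysis and methanogenesis
#'
#' \deqn{D_{efficiency} = (hyd - meth) / hyd.}
#' Positive values indicate hydrolysis outpacing methanogenesis (intermediate
#' accumulation); zero indicates balance.
#'
#' @param hyd Hydrolysis efficiency (fraction or percent, consistent units).
#' @param meth Methanogenesis efficiency in the same units.
#' @return Dimensionless relative difference. Vectorised.
#' @export
d_efficiency <- function(hyd, meth) {
  if (any(!is.finite(hyd)) || any(!is.finite(meth)))
    stop("non-finite efficiency", call. = FALSE)
  if (any(hyd == 0))
    stop("D_efficiency undefined when hydrolysis efficiency is 0", call. = FALSE)
  (hyd - meth) / hyd
}

#' Relative differential rate between hydrolysis and methanogenic capacity
#'
#' \deqn{D_{rate} = (K_H - SMA) / K_H.}
#' Contrasts how readily the substrate hydrolyses (K_H) with the sludge's
#' total specific methanogenic activity (SMA); large positive values flag a
#' methanogenesis bottleneck.
#'
#' @param K_H First-order hydrolysis rate constant, 1/day.
#' @param SMA Total specific methanogenic activity, gCOD/gVSS/day.
#' @return Dimensionless relative difference. Vectorised.
#' @export
d_rate <- function(K_H, SMA) {
  if (any(!is.finite(K_H)) || any(!is.finite(SMA)))
    stop("non-finite rate", call. = FALSE)
  if (any(K_H == 0))
    stop("D_rate undefined when K_H is 0", call. = FALSE)
  (K_H - SMA) / K_H
}

#' Derived reactor performance metrics from measured chemistry
#'
#' Assembles the full derived-metric table from per-reactor (or per-stage)
#' chemistry measurements: free ammonia, hydrolysis and methanogenesis
#' efficiency, particulate COD ratio of the influent, and — where K_H and SMA
#' are available — the relative differential efficiency and rate.
#'
#' Metrics computed from stage-mean inputs generally differ from means of
#' per-sample metrics (the transformations are nonlinear); pass per-sample
#' rows and average afterwards when that distinction matters.
#'
#' @param chem A data frame with columns `tCOD_inf`, `tCOD_eff`, `sCOD_inf`,
#'   `sCOD_eff`, `COD_CH4`, `TAN`, `pH`, `temperature_C`, and optionally
#'   `SMA_total` and `K_H`. Any identifier columns (e.g. `reactor_id`,
#'   `group`, `stage`) are carried through.
#' @return A data frame with the identifier columns plus `FA`,
#'   `hydrolysis_eff`, `methanogenesis_eff`, `pCOD_ratio`, `D_efficiency`,
#'   and, when inputs permit, `K_H` and `D_rate`.
#' @export
derive_metrics <- function(chem) {
  required <- c("tCOD_inf", "tCOD_eff", "sCOD_inf", "sCOD_eff",
                "COD_CH4", "TAN", "pH", "temperature_C")
  missing_cols <- setdiff(required, names(chem))
  if (length(missing_cols))
    stop("derive_metrics: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(chem$sCOD_inf > chem$tCOD_inf + 1e-9))
    stop("sCOD_inf exceeds tCOD_inf", call. = FALSE)
  if (any(chem$sCOD_eff > chem$tCOD_eff + 1e-9))
    stop("sCOD_eff exceeds tCOD_eff", call. = FALSE)
  id_cols <- setdiff(names(chem), c(required, "SMA_total", "SMA_obs", "K_H"))
  out <- chem[, id_cols, drop = FALSE]
  out$FA <- free_ammonia(chem$TAN, chem$pH, chem$temperature_C)
  out$hydrolysis_eff <- hydrolysis_efficiency(
    chem$sCOD_eff, chem$sCOD_inf, chem$COD_CH4, chem$tCOD_inf, chem$tCOD_eff)
  out$methanogenesis_eff <- methanogenesis_efficiency(
    chem$COD_CH4, chem$tCOD_inf, chem$tCOD_eff)
  out$pCOD_ratio <- 1 - chem$sCOD_inf / chem$tCOD_inf
  out$D_efficiency <- d_efficiency(out$hydrolysis_eff, out$methanogenesis_eff)
  if ("K_H" %in% names(chem)) {
    out$K_H <- chem$K_H
    if ("SMA_total" %in% names(chem))
      out$D_rate <- d_rate(chem$K_H, chem$SMA_total)
  }
  if ("SMA_total" %in% names(chem)) out$SMA_total <- chem$SMA_total
  if ("SMA_obs" %in% names(chem)) out$SMA_obs <- chem$SMA_obs
  if ("tCOD_inf" %in% names(chem)) out$tCOD_inf <- chem$tCOD_inf
  if ("sCOD_inf" %in% names(chem)) out$sCOD_inf <- chem$sCOD_inf
  out
}

#' Read long-format reactor chemistry
#'
#' Reads a long/tidy TSV with columns `reactor_id`, `stage`, `variable`,
#' `value`, `unit` and pivots it to the wide per-reactor-stage layout
#' expected by [derive_metrics()].
#'
#' @param path Path to a tab-separated file.
#' @return Wide data frame, one row per (reactor_id, stage).
#' @export
read_chem_long <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reactor_id", "stage", "variable", "value")
  if (!all(need %in% names(long)))
    stop("expected columns reactor_id, stage, variable, value", call. = FALSE)
  wide <- stats::reshape(
    long[, c("reactor_id", "stage", "variable", "value")],
    idvar = c("reactor_id", "stage"), timevar = "variable",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Write a derived-metrics table as TSV
#'
#' @param metrics Data frame from [derive_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_derived_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
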