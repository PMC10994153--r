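#' Archetype mean curves for synthetic OGTT glucose responses
#'
#' Each archetype is a minimal smooth curve that triggers exactly one rule
#' of the shape classifier when sampled noise-free at 0/30/60/90/120 min:
#' \describe{
#'   \item{monophasic}{single peak at 60 min returning partway to fasting;}
#'   \item{biphasic}{early peak at 30 min, dip at 60, secondary rise by
#'     120;}
#'   \item{monotonic}{strictly increasing to 120 min;}
#'   \item{flat}{no rise at all (feeds the inconclusive path).}
#' }
#' The curve through the five control values is a natural cubic spline, so
#' the generator can be evaluated at any time in [0, 120] (used for the
#' delayed insulin transform and the latent 120-min excursion).
#'
#' @param name one of "monophasic", "biphasic", "monotonic", "flat".
#' @param fasting fasting glucose in mg/dL (curve value at 0 min).
#' @param amplitude excursion scale in mg/dL.
#' @return list of class \code{ogtt_archetype}: name, the five control
#'   values at the sampling times, and \code{fn}, the mean curve as a
#'   function of time.
#' @export
ogtt_archetype <- function(name = c("monophasic", "biphasic", "monotonic", "flat"),
                           fasting, amplitude) {
  name <- match.arg(name)
  frac <- archetype_fractions()[[name]]
  values <- fasting + amplitude * frac
  fn <- stats::splinefun(c(0, 30, 60, 90, 120), values, method = "natural")
  structure(list(name = name, values = values, fasting = fasting,
                 amplitude = amplitude, fn = fn),
            class = "ogtt_archetype")
}

# excursion fractions at 0/30/60/90/120 min; chosen so the noise-free
# series classifies deterministically for any amplitude >= 20 mg/dL
# (biphasic dip 0.35*A >= 4.5 and re-rise 0.25*A >= 4.5 need A >= 18)
archetype_fractions <- function() {
  list(monophasic = c(0, 0.55, 1.00, 0.65, 0.35),
       biphasic   = c(0, 0.90, 0.55, 0.80, 0.90),
       monotonic  = c(0, 0.30, 0.55, 0.80, 1.00),
       flat       = c(0, 0, 0, 0, 0))
}

#' Parameters of the synthetic OGTT cohort generator
#'
#' Defaults emulate a pediatric cohort with overweight/obesity: shape-class
#' mixture 54.7/42.0/2.5/0.8\% (monophasic/biphasic/monotonic/flat),
#' fasting glucose ~ N(83, 8) mg/dL, 53.9\% female, ages uniform on 8-18,
#' BMI percentile concentrated near the 97th, 28.8\% with a follow-up visit
#' and a follow-up dysglycemia prevalence calibrated to 7.3\%. Metabolic
#' labs are generated with positive dependence on the latent glucose
#' excursion so that curve-height associations are recoverable. The outcome
#' model places its weight on the latent curve excursion and the 120-min
#' excursion above fasting, and none on fasting glucose itself, so fasting
#' glucose is uninformative for future dysglycemia by construction.
#'
#' @param n cohort size.
#' @param mixture named archetype probabilities (must sum to 1).
#' @param fasting_mean,fasting_sd fasting glucose distribution (mg/dL).
#' @param amplitude named list of c(mean, sd, min) excursion amplitude
#'   (mg/dL) per archetype.
#' @param insulin_gain0 median multiplicative insulin gain.
#' @param insulin_basal_median median basal insulin signal (uU/mL at unit
#'   gain).
#' @param insulin_delay insulin peak delay behind glucose, minutes.
#' @param noise_sd_glucose measurement noise SD, mg/dL.
#' @param noise_sd_insulin measurement noise SD on the pre-gain insulin
#'   signal.
#' @param followup_fraction probability of a follow-up visit.
#' @param outcome list: \code{beta_height} and \code{beta_g120} log-odds
#'   coefficients on the standardized latent excursion and 120-min
#'   excursion, and target \code{prevalence} used to calibrate the
#'   intercept.
#' @param missing list of missingness probabilities for blood pressure,
#'   waist circumference and lipid labs.
#' @param seed master seed; per-participant substreams are derived from it
#'   so that enlarging the cohort does not perturb existing participants.
#' @return list of class \code{ogtt_genparams}.
#' @export
generator_params <- function(n = 500L,
                             mixture = c(monophasic = 0.547, biphasic = 0.420,
                                         monotonic = 0.025, flat = 0.008),
                             fasting_mean = 83, fasting_sd = 8,
                             amplitude = list(monophasic = c(55, 12, 20),
                                              biphasic = c(45, 10, 20),
                                              monotonic = c(60, 12, 25),
                                              flat = c(0, 0, 0)),
                             insulin_gain0 = 1.5,
                             insulin_basal_median = 8,
                             insulin_delay = 15,
                             noise_sd_glucose = 4,
                             noise_sd_insulin = 3,
                             followup_fraction = 0.288,
                             outcome = list(beta_height = 0.9, beta_g120 = 0.9,
                                            prevalence = 0.073),
                             missing = list(bp = 0.031, waist = 0.036, lipids = 0.015),
                             seed = 1L) {
  if (n <= 0) stop("`n` must be positive")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(mixture < 0)) stop("mixture weights must be non-negative")
  if (noise_sd_glucose < 0 || noise_sd_insulin < 0) stop("noise SDs must be >= 0")
  if (followup_fraction < 0 || followup_fraction > 1) {
    stop("`followup_fraction` must be in [0, 1]")
  }
  structure(
    list(n = as.integer(n), mixture = mixture, fasting_mean = fasting_mean,
         fasting_sd = fasting_sd, amplitude = amplitude,
         insulin_gain0 = insulin_gain0,
         insulin_basal_median = insulin_basal_median,
         insulin_delay = insulin_delay,
         noise_sd_glucose = noise_sd_glucose,
         noise_sd_insulin = noise_sd_insulin,
         followup_fraction = followup_fraction, outcome = outcome,
         missing = missing, seed = as.integer(seed)),
    class = "ogtt_genparams")
}

# deterministic 32-bit substream seed for participant i
substream_seed <- function(seed, i, salt = 0L) {
  (as.double(seed %% 65011) * 33029 + as.double(i) * 2017 + salt) %% 2147483647
}

#' Generate one participant's OGTT profile from an archetype
#'
#' Glucose: archetype mean curve at the five sampling times plus Gaussian
#' measurement noise, truncated at a 40 mg/dL physiological floor. Insulin:
#' gain times a delayed copy of the glucose excursion plus a basal level
#' and noise, floored at 1 uU/mL. The pre-floor insulin values are exactly
#' proportional to \code{insulin_gain} (basal and noise sit inside the
#' gain), which keeps the generator linear in the gain.
#'
#' Uses the current RNG state; seed the stream before calling for
#' reproducibility.
#'
#' @param archetype an \code{ogtt_archetype}.
#' @param insulin_gain per-participant multiplicative gain.
#' @param insulin_basal basal insulin signal at unit gain.
#' @param insulin_delay delay in minutes of the insulin response behind the
#'   glucose excursion.
#' @param noise_sd_glucose,noise_sd_insulin Gaussian noise SDs (insulin
#'   noise on the pre-gain signal).
#' @return list with \code{times}, \code{glucose}, \code{insulin}.
#' @export
generate_profile <- function(archetype, insulin_gain, insulin_basal = 8,
                             insulin_delay = 15, noise_sd_glucose = 4,
                             noise_sd_insulin = 3) {
  stopifnot(inherits(archetype, "ogtt_archetype"))
  times <- c(0, 30, 60, 90, 120)
  glucose <- pmax(archetype$values + stats::rnorm(5, 0, noise_sd_glucose), 40)
  exc <- archetype$fn(pmax(times - insulin_delay, 0)) - archetype$fasting
  signal <- insulin_basal + pmax(exc, 0) + stats::rnorm(5, 0, noise_sd_insulin)
  insulin <- pmax(insulin_gain * signal, 1)
  list(times = times, glucose = glucose, insulin = insulin)
}

#' Generate a seeded synthetic OGTT cohort
#'
#' Draws \code{params$n} participants. Each participant has a private RNG
#' substream derived from the master seed, so generated records are stable
#' under cohort enlargement. Demographics follow the default margins
#' (53.9\% female; race 57.5/31.6/7.8/3.1\% white/black/other/unknown;
#' 5.8\% Hispanic; ages uniform 8-18). Metabolic labs depend positively on
#' the latent curve excursion. Follow-up outcomes are attached by
#' [assign_followup()].
#'
#' @param params an \code{ogtt_genparams} from [generator_params()].
#' @return data.frame of class \code{ogtt_cohort} in the wide dialect (one
#'   row per participant), with a ground-truth sidecar in
#'   \code{attr(, "truth")}: archetype, latent excursion, event
#'   probability.
#' @examples
#' coh <- generate_cohort(generator_params(n = 50, seed = 1))
#' table(attr(coh, "truth")$archetype)
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "ogtt_genparams"))
  n <- params$n
  arch_names <- names(params$mixture)
  num <- function() numeric(n)
  chr <- function() character(n)
  v <- list(age = num(), sex = chr(), race = chr(), ethnicity = chr(),
            bmi = num(), waist = num(), sbp = num(), dbp = num(),
            hba1c = num(), tchol = num(), ldl = num(), hdl = num(),
            trig = num(), has_fu = logical(n), fu_interval = num())
  Gm <- matrix(NA_real_, n, 5)
  Im <- matrix(NA_real_, n, 5)
  tv <- list(archetype = chr(), fasting = num(), amplitude = num(),
             height = num(), e120 = num(), gain = num(), u_event = num())
  for (i in seq_len(n)) {
    set.seed(substream_seed(params$seed, i))
    arch <- sample(arch_names, 1L, prob = params$mixture)
    fasting <- max(stats::rnorm(1, params$fasting_mean, params$fasting_sd), 55)
    amp_par <- params$amplitude[[arch]]
    amplitude <- if (arch == "flat") 0 else
      max(stats::rnorm(1, amp_par[1], amp_par[2]), amp_par[3])
    archetype <- ogtt_archetype(arch, fasting, amplitude)
    # latent excursion drivers (fasting-free by design)
    height <- mean(archetype$values) - fasting
    hz <- (height - 28) / 9
    e120 <- archetype$fn(120) - fasting

    age <- stats::runif(1, 8, 18)
    sex <- sample(c("female", "male"), 1L, prob = c(0.539, 0.461))
    race <- sample(c("white", "black", "other/multiracial", "unknown"), 1L,
                   prob = c(0.575, 0.316, 0.078, 0.031))
    ethnicity <- sample(c("non-hispanic", "hispanic"), 1L, prob = c(0.942, 0.058))
    u_bmi <- stats::pnorm((0.4 * hz + stats::rnorm(1)) / sqrt(1 + 0.4^2))
    bmi <- 85 + 15 * stats::qbeta(u_bmi, 4, 1.2)

    gain <- params$insulin_gain0 *
      exp(0.05 * (bmi - 97) + stats::rnorm(1, 0, 0.3))
    basal <- params$insulin_basal_median * exp(stats::rnorm(1, 0, 0.3))
    prof <- generate_profile(archetype, insulin_gain = gain,
                             insulin_basal = basal,
                             insulin_delay = params$insulin_delay,
                             noise_sd_glucose = params$noise_sd_glucose,
                             noise_sd_insulin = params$noise_sd_insulin)

    hba1c <- max(5.2 + 0.12 * hz + stats::rnorm(1, 0, 0.25), 3.8)
    trig <- exp(log(90) + 0.18 * hz + stats::rnorm(1, 0, 0.35))
    tchol <- max(160 + 6 * hz + stats::rnorm(1, 0, 25), 80)
    hdl <- max(48 - 3 * hz + stats::rnorm(1, 0, 9), 15)
    ldl <- max(95 + 5 * hz + stats::rnorm(1, 0, 22), 30)
    sbp <- 112 + 1.5 * hz + stats::rnorm(1, 0, 10)
    dbp <- 68 + 1.0 * hz + stats::rnorm(1, 0, 8)
    waist <- max(88 + 1.3 * (bmi - 97) + 0.8 * hz + stats::rnorm(1, 0, 8), 50)

    miss <- stats::runif(3)
    if (miss[1] < params$missing$bp) sbp <- dbp <- NA_real_
    if (miss[2] < params$missing$waist) waist <- NA_real_
    if (miss[3] < params$missing$lipids) tchol <- ldl <- hdl <- trig <- NA_real_

    has_fu <- stats::runif(1) < params$followup_fraction
    fu_interval <- if (has_fu) stats::rlnorm(1, log(14), 0.35) else NA_real_
    u_event <- stats::runif(1)

    v$age[i] <- age; v$sex[i] <- sex; v$race[i] <- race
    v$ethnicity[i] <- ethnicity; v$bmi[i] <- bmi; v$waist[i] <- waist
    v$sbp[i] <- sbp; v$dbp[i] <- dbp; v$hba1c[i] <- hba1c
    v$tchol[i] <- tchol; v$ldl[i] <- ldl; v$hdl[i] <- hdl; v$trig[i] <- trig
    v$has_fu[i] <- has_fu; v$fu_interval[i] <- fu_interval
    Gm[i, ] <- prof$glucose
    Im[i, ] <- prof$insulin
    tv$archetype[i] <- arch; tv$fasting[i] <- fasting
    tv$amplitude[i] <- amplitude; tv$height[i] <- height
    tv$e120[i] <- e120; tv$gain[i] <- gain; tv$u_event[i] <- u_event
  }
  ids <- sprintf("P%05d", seq_len(n))
  cohort <- data.frame(
    id = ids, age = v$age, sex = v$sex, race = v$race,
    ethnicity = v$ethnicity, bmi_percentile = v$bmi, waist_cm = v$waist,
    sbp = v$sbp, dbp = v$dbp, hba1c = v$hba1c, total_chol = v$tchol,
    ldl = v$ldl, hdl = v$hdl, triglycerides = v$trig,
    stringsAsFactors = FALSE)
  cohort[gcols("glucose")] <- as.data.frame(Gm)
  cohort[gcols("insulin")] <- as.data.frame(Im)
  cohort$has_followup <- v$has_fu
  cohort$followup_interval <- v$fu_interval
  truth <- data.frame(
    id = ids, archetype = tv$archetype, fasting = tv$fasting,
    amplitude = tv$amplitude, latent_height = tv$height, e120 = tv$e120,
    insulin_gain = tv$gain, u_event = tv$u_event, stringsAsFactors = FALSE)
  cohort <- assign_followup(cohort, truth, params)
  class(cohort) <- c("ogtt_cohort", "data.frame")
  cohort
}

#' Attach follow-up outcomes to a synthetic cohort
#'
#' For participants with a follow-up visit, the probability of dysglycemia
#' at follow-up is \eqn{logit^{-1}(\alpha + \beta_h h_i + \beta_g e_i)}
#' where \eqn{h_i} is the standardized latent curve excursion and
#' \eqn{e_i} the standardized 120-min excursion above fasting. The
#' intercept \eqn{\alpha} is calibrated so that the mean event probability
#' over the follow-up subset equals the target prevalence (with all
#' coefficients zero this reduces to \eqn{\alpha = logit(p)}). Follow-up
#' fasting and 2-h glucose are then drawn consistent with the event label
#' (event: FPG > 100 or 2hrPG > 140), independent of baseline fasting
#' glucose. A full follow-up profile, HbA1c and BMI percentile are attached
#' for paired baseline/follow-up testing.
#'
#' @param cohort cohort data.frame from the generator loop.
#' @param truth ground-truth sidecar (archetype, latent excursion,
#'   pre-drawn event uniform).
#' @param params an \code{ogtt_genparams}.
#' @return the cohort with \code{fu_*} columns filled and \code{truth}
#'   (including \code{event_prob}) stored in \code{attr(, "truth")}.
#' @export
assign_followup <- function(cohort, truth, params) {
  n <- nrow(cohort)
  fu <- which(cohort$has_followup)
  out <- params$outcome
  eta <- rep(NA_real_, n)
  if (length(fu) > 0) {
    hz <- scale_safe(truth$latent_height[fu])
    ez <- scale_safe(truth$e120[fu])
    lin <- out$beta_height * hz + out$beta_g120 * ez
    alpha <- calibrate_intercept(lin, out$prevalence)
    eta[fu] <- alpha + lin
  }
  p_event <- stats::plogis(eta)
  event <- !is.na(p_event) & truth$u_event < p_event

  fuG <- matrix(NA_real_, n, 5)
  fuI <- matrix(NA_real_, n, 5)
  fu_hba1c <- rep(NA_real_, n)
  fu_bmi <- rep(NA_real_, n)

  for (i in fu) {
    set.seed(substream_seed(params$seed, i, salt = 7L))
    if (event[i]) {
      fpg_route <- stats::runif(1) < 0.35
      fpg2 <- if (fpg_route) 100.5 + stats::rexp(1, 1 / 4) else rtrunc_upper(88, 5, 100)
      pg2h2 <- if (fpg_route) 120 + stats::rexp(1, 1 / 20) else 140.5 + stats::rexp(1, 1 / 12)
    } else {
      fpg2 <- rtrunc_upper(86, 5, 100)
      pg2h2 <- rtrunc_upper(102, 16, 140)
    }
    mid <- max(fpg2, pg2h2) + 25 + abs(stats::rnorm(1, 0, 8))
    g <- c(fpg2, fpg2 + 0.7 * (mid - fpg2), mid, (mid + pg2h2) / 2, pg2h2)
    g[2:4] <- pmax(g[2:4] + stats::rnorm(3, 0, params$noise_sd_glucose), 40)
    ins <- pmax(truth$insulin_gain[i] *
                  (params$insulin_basal_median + pmax(g - fpg2, 0) +
                     stats::rnorm(5, 0, params$noise_sd_insulin)), 1)
    fuG[i, ] <- g
    fuI[i, ] <- ins
    fu_hba1c[i] <- max(cohort$hba1c[i] + 0.1 + stats::rnorm(1, 0, 0.15), 3.8)
    fu_bmi[i] <- min(max(cohort$bmi_percentile[i] + stats::rnorm(1, 0, 1.5), 85), 99.9)
  }
  cohort[gcols("fu_glucose")] <- as.data.frame(fuG)
  cohort[gcols("fu_insulin")] <- as.data.frame(fuI)
  cohort$fu_hba1c <- fu_hba1c
  cohort$fu_bmi_percentile <- fu_bmi
  truth$event_prob <- p_event
  truth$fu_event <- event
  attr(cohort, "truth") <- truth
  cohort
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# intercept alpha with mean(plogis(alpha + lin)) = target
calibrate_intercept <- function(lin, target) {
  if (all(lin == lin[1])) return(stats::qlogis(target) - lin[1])
  f <- function(a) mean(stats::plogis(a + lin)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

# truncated normal draw below `upper`, via inverse CDF
rtrunc_upper <- function(mean, sd, upper) {
  u <- stats::runif(1) * stats::pnorm((upper - mean) / sd)
  stats::qnorm(u) * sd + mean
}

#' @export
print.ogtt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic OGTT cohort: %d participants, %d with follow-up\n",
              nrow(x), sum(x$has_followup)))
  tr <- attr(x, "truth")
  if (!is.null(tr)) {
    tab <- table(tr$archetype)
    cat("  archetypes:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
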