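#' Default configuration for a synthetic infant cohort
#'
#' The generator emulates the statistical structure the analysis assumes:
#' three composition regimes (Bifidobacteriaceae-, Enterobacteriaceae- and
#' Staphylococcaceae-dominated), a forward-biased daily Markov chain over
#' the regimes (S -> E -> B succession with rare reversals), Dirichlet
#' compositions resampled through a multinomial at finite sequencing depth,
#' and gut-environment variables monotonically coupled to Bifidobacteriaceae
#' abundance: acetate rises, pH falls, and residual oligosaccharide falls
#' when the subject carries FL-utilizing bifidobacteria (`flu` flag).
#'
#' @param n_subjects number of longitudinally sampled subjects (default 12).
#' @param days sampling schedule per subject (default: daily for week one,
#'   then every other day to day 29 — 18 samples).
#' @param taxa taxon (family) names; the first three are the regime
#'   dominants.
#' @param dominant_concentration,background_concentration Dirichlet
#'   concentration of the regime's dominant taxon and of every other taxon
#'   (defaults 24 and 1: dominant mean ~0.73).
#' @param initial_probs initial regime distribution over S, E, B.
#' @param forward_rate,backward_rate daily probabilities of moving one step
#'   forward (S->E, E->B) or backward (E->S, B->E) in the succession
#'   (defaults 0.15 and 0.01).
#' @param depth multinomial resampling depth (reads per sample, default 2000).
#' @param p_flu probability that a subject is colonized by FL-utilizing
#'   bifidobacteria (default 0.6).
#' @param acetate_base,acetate_slope,acetate_sd acetate (mM) coupling:
#'   `acetate = base + slope * bifido + N(0, sd)`, truncated at 0.
#' @param ph_base,ph_slope,ph_sd pH coupling: `pH = base - slope * bifido
#'   + N(0, sd)`, clamped to (0, 14).
#' @param oligo_base,oligo_utilization,oligo_sd residual oligosaccharide
#'   (mM): `oligo = base * (1 - u * flu * bifido) + N(0, sd)`, truncated
#'   at 0.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12,
                          days = c(1:7, seq(9, 29, by = 2)),
                          taxa = c("Bifidobacteriaceae", "Enterobacteriaceae",
                                   "Staphylococcaceae", "Enterococcaceae",
                                   "Streptococcaceae", "Clostridiaceae",
                                   "Lactobacillaceae", "Bacteroidaceae",
                                   "Veillonellaceae", "Peptostreptococcaceae"),
                          dominant_concentration = 24,
                          background_concentration = 1,
                          initial_probs = c(S = 0.5, E = 0.4, B = 0.1),
                          forward_rate = 0.15, backward_rate = 0.01,
                          depth = 2000, p_flu = 0.6,
                          acetate_base = 15, acetate_slope = 60, acetate_sd = 8,
                          ph_base = 6.8, ph_slope = 1.8, ph_sd = 0.25,
                          oligo_base = 20, oligo_utilization = 0.9, oligo_sd = 2) {
  if (length(taxa) < 3) stop("need at least 3 taxa (one per regime)")
  if (forward_rate < 0 || backward_rate < 0 ||
      forward_rate + backward_rate > 1)
    stop("invalid transition rates")
  if (abs(sum(initial_probs) - 1) > 1e-9) stop("initial_probs must sum to 1")
  if (acetate_slope < 0 || ph_slope < 0 || oligo_utilization < 0)
    stop("couplings must be non-negative")
  structure(as.list(environment()), class = "cohort_config")
}

# 3x3 daily transition matrix over S, E, B from the one-step rates
transition_matrix_config <- function(config) {
  f <- config$forward_rate; b <- config$backward_rate
  m <- matrix(c(1 - f, f,         0,
                b,     1 - f - b, f,
                0,     b,         1 - b),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("S", "E", "B"), c("S", "E", "B")))
  m
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic longitudinal infant cohort
#'
#' See [cohort_config()] for the generative model. Fully reproducible from
#' `seed` (the only source of randomness).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `table` ([abundance_table()]), `meta`
#'   ([sample_metadata()], including the per-subject `flu` flag), `env`
#'   ([environment_table()]: acetate_mM, pH, oligo_mM), and `truth`
#'   (data.frame of the generating regime per sample).
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("seed is required")
  regimes <- c("S", "E", "B")
  dominant_taxon <- c(S = config$taxa[3], E = config$taxa[2], B = config$taxa[1])
  tm <- transition_matrix_config(config)
  if (any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
    stop("invalid transition matrix")
  withr::with_seed(as.integer(seed), {
    rows <- list(); meta_rows <- list(); env_rows <- list(); truth_rows <- list()
    for (s in seq_len(config$n_subjects)) {
      subject <- sprintf("subj_%02d", s)
      flu <- stats::rbinom(1, 1, config$p_flu)
      state <- sample(regimes, 1, prob = config$initial_probs)
      prev_day <- 0
      for (d in config$days) {
        # advance the daily chain across the gap since the last sample
        for (step in seq_len(d - prev_day))
          state <- sample(regimes, 1, prob = tm[state, ])
        prev_day <- d
        alpha <- rep(config$background_concentration, length(config$taxa))
        names(alpha) <- config$taxa
        alpha[dominant_taxon[state]] <- config$dominant_concentration
        p <- rdirichlet1(alpha)
        counts <- stats::rmultinom(1, size = config$depth, prob = p)[, 1]
        # a depth-resampled all-zero draw cannot occur (depth >= 1)
        frac <- counts / sum(counts)
        names(frac) <- config$taxa
        sid <- sprintf("%s_d%02d", subject, d)
        rows[[sid]] <- frac
        bif <- frac[["Bifidobacteriaceae"]]
        acetate <- max(0, config$acetate_base + config$acetate_slope * bif +
                         stats::rnorm(1, 0, config$acetate_sd))
        ph <- min(13.99, max(0.01, config$ph_base - config$ph_slope * bif +
                               stats::rnorm(1, 0, config$ph_sd)))
        oligo <- max(0, config$oligo_base *
                       (1 - config$oligo_utilization * flu * bif) +
                       stats::rnorm(1, 0, config$oligo_sd))
        meta_rows[[sid]] <- data.frame(sample_id = sid, subject_id = subject,
                                       day = d, flu = flu,
                                       stringsAsFactors = FALSE)
        env_rows[[sid]] <- data.frame(sample_id = sid, acetate_mM = acetate,
                                      pH = ph, oligo_mM = oligo,
                                      stringsAsFactors = FALSE)
        truth_rows[[sid]] <- data.frame(sample_id = sid, subject_id = subject,
                                        day = d, regime = state,
                                        stringsAsFactors = FALSE)
      }
    }
  })
  values <- do.call(rbind, rows)
  colnames(values) <- config$taxa
  meta_df <- do.call(rbind, c(meta_rows, make.row.names = FALSE))
  env_df <- do.call(rbind, c(env_rows, make.row.names = FALSE))
  list(
    table = abundance_table(values),
    meta = sample_metadata(meta_df$sample_id, meta_df$subject_id,
                           meta_df$day, "infant_longitudinal",
                           flu = meta_df$flu),
    env = environment_table(env_df$sample_id, acetate_mM = env_df$acetate_mM,
                            pH = env_df$pH, oligo_mM = env_df$oligo_mM),
    truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)),
    config = config, seed = as.integer(seed)
  )
}

#' Default configuration for a synthetic strain panel
#'
#' Emulates a pan-genome presence/absence panel with one planted
#' phenotype-discriminating homologous group: the planted column equals the
#' grower phenotype with a bounded number of exception strains flipped;
#' every other group is i.i.d. Bernoulli background. Growth curves are
#' logistic with class-dependent carrying capacity (above/below the 0.7/0.3
#' saturating-OD thresholds) plus truncated Gaussian noise.
#'
#' @param n_strains panel size (default 29).
#' @param n_groups number of homologous groups (default 2000).
#' @param background_p background presence probability (default 0.5).
#' @param n_growers number of grower strains (default 14).
#' @param n_exceptions planted exception strains (default 1).
#' @param exception_direction `"absent_but_grower"` (default, mirroring an
#'   extracellular-fucosidase utilizer lacking the transporter) or
#'   `"present_but_non_grower"`.
#' @param grower_capacity,non_grower_capacity logistic carrying capacities
#'   (defaults 0.9 and 0.15).
#' @param growth_rate logistic rate per hour (default 0.35).
#' @param noise_sd OD noise sd (default 0.02).
#' @param times curve time grid in hours (default 0..40 by 1).
#' @param replicates technical replicates per strain (default 2).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(n_strains = 29, n_groups = 2000, background_p = 0.5,
                         n_growers = 14, n_exceptions = 1,
                         exception_direction = c("absent_but_grower",
                                                 "present_but_non_grower"),
                         grower_capacity = 0.9, non_grower_capacity = 0.15,
                         growth_rate = 0.35, noise_sd = 0.02,
                         times = seq(0, 40, by = 1), replicates = 2) {
  exception_direction <- match.arg(exception_direction)
  if (n_exceptions >= n_strains / 2) stop("too many planted exceptions")
  if (n_growers < 2 || n_strains - n_growers < 2)
    stop("need at least 2 strains per phenotype class")
  if (grower_capacity <= 0.7 || non_grower_capacity >= 0.3)
    stop("capacities must be consistent with the 0.7/0.3 thresholds")
  structure(as.list(environment()), class = "panel_config")
}

#' Generate a synthetic strain panel
#'
#' @param config a [panel_config()].
#' @param seed integer seed.
#' @return list with `presence` (`gene_presence_matrix`), `phenotype`
#'   (named grower/non_grower vector), `curves` (long data.frame:
#'   strain_id, replicate, time_h, od600), `planted_group` (group id) and
#'   `exception_strains`.
#' @export
generate_strain_panel <- function(config = panel_config(), seed) {
  stopifnot(inherits(config, "panel_config"))
  if (missing(seed)) stop("seed is required")
  strains <- sprintf("ST-%02d", seq_len(config$n_strains))
  groups <- sprintf("HG_%04d", seq_len(config$n_groups))
  withr::with_seed(as.integer(seed), {
    grower_idx <- sample.int(config$n_strains, config$n_growers)
    y <- rep("non_grower", config$n_strains)
    y[grower_idx] <- "grower"
    names(y) <- strains
    m <- matrix(stats::rbinom(config$n_strains * config$n_groups, 1,
                              config$background_p),
                nrow = config$n_strains,
                dimnames = list(strains, groups))
    planted <- sample(groups, 1)
    col <- as.integer(y == "grower")
    exc_pool <- if (config$exception_direction == "absent_but_grower")
      which(col == 1) else which(col == 0)
    if (config$n_exceptions > length(exc_pool))
      stop("planted exceptions exceed the phenotype class size")
    exc <- sample(exc_pool, config$n_exceptions)
    col[exc] <- 1L - col[exc]
    m[, planted] <- col
    curves <- do.call(rbind, lapply(seq_along(strains), function(i) {
      cap <- if (y[i] == "grower") config$grower_capacity
             else config$non_grower_capacity
      do.call(rbind, lapply(seq_len(config$replicates), function(r) {
        od0 <- 0.01
        od <- cap / (1 + ((cap - od0) / od0) *
                       exp(-config$growth_rate * config$times))
        od <- pmax(0, od + stats::rnorm(length(od), 0, config$noise_sd))
        data.frame(strain_id = strains[i], replicate = r,
                   time_h = config$times, od600 = od,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  list(presence = structure(m, class = c("gene_presence_matrix", "matrix", "array")),
       phenotype = y, curves = curves, planted_group = planted,
       exception_strains = strains[exc], config = config,
       seed = as.integer(seed))
}
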