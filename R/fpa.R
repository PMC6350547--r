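#' Flower pollination algorithm configuration
#'
#' Parameters of the learning-rate search: population size, iteration
#' count, the cross/self-pollination switch probability, the Levy-flight
#' scaling factor gamma (0.1) and tail exponent (1.5), and the search
#' interval for the learning rate.
#'
#' @param n_iterations Number of FPA iterations N (>= 1).
#' @param n_pollen Population size m (>= 2).
#' @param switch_prob Probability P_C of choosing the global
#'   (cross-pollination) move over the local (self-pollination) move.
#' @param gamma Scaling factor of the Levy step in the global move.
#' @param levy_exponent Tail exponent of the Levy distribution, in (1, 2].
#' @param lr_min,lr_max Learning-rate search bounds, 0 < lr_min < lr_max.
#' @return An object of class `fpa_config`.
#' @export
fpa_config <- function(n_iterations = 10L, n_pollen = 10L,
                       switch_prob = 0.8, gamma = 0.1,
                       levy_exponent = 1.5,
                       lr_min = 1e-4, lr_max = 0.5) {
  assert_that(n_iterations >= 1, "n_iterations must be >= 1")
  assert_that(n_pollen >= 2, "n_pollen must be >= 2")
  assert_that(switch_prob >= 0 && switch_prob <= 1,
              "switch_prob must be in [0, 1]")
  assert_that(gamma > 0, "gamma must be positive")
  assert_that(levy_exponent > 1 && levy_exponent <= 2,
              "levy_exponent must be in (1, 2]")
  assert_that(lr_min > 0 && lr_min < lr_max,
              "learning-rate bounds must satisfy 0 < lr_min < lr_max")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_pollen = as.integer(n_pollen),
                 switch_prob = switch_prob, gamma = gamma,
                 levy_exponent = levy_exponent,
                 lr_min = lr_min, lr_max = lr_max),
            class = "fpa_config")
}

#' Draw one Levy-flight step
#'
#' Samples a heavy-tailed step by Mantegna's algorithm:
#' `L = u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and
#' `sigma_u` set by the Mantegna formula for tail exponent `beta`, so
#' that |L| has power-law tails with index `beta`.
#'
#' @param exponent Tail exponent beta in (1, 2]; default 1.5.
#' @param n Number of draws.
#' @return Numeric vector of `n` Levy steps. Uses R's global RNG stream.
#' @export
levy_sample <- function(exponent = 1.5, n = 1L) {
  assert_that(exponent > 1 && exponent <= 2,
              "exponent must be in (1, 2]")
  beta <- exponent
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n, 0, 1)
  u / abs(v)^(1 / beta)
}

#' Global (cross-pollination) move toward the best learning rate
#'
#' Proposes `l_i + gamma * L * (l_best - l_i)` with `L` one Levy draw,
#' clamped to the search bounds. The incumbent best is a fixed point.
#'
#' @param l_i Current pollen (learning rate).
#' @param l_best Best learning rate found so far.
#' @param gamma Scaling factor (default 0.1).
#' @param exponent Levy tail exponent (default 1.5).
#' @param lr_min,lr_max Clamping bounds.
#' @return Candidate learning rate within bounds.
#' @export
cross_pollinate <- function(l_i, l_best, gamma = 0.1, exponent = 1.5,
                            lr_min = 1e-4, lr_max = 0.5) {
  assert_that(is.finite(l_i) && is.finite(l_best), "inputs must be finite")
  assert_that(gamma >= 0, "gamma must be non-negative")
  L <- levy_sample(exponent, 1L)
  clamp(l_i + gamma * L * (l_best - l_i), lr_min, lr_max)
}

#' Local (self-pollination) move between two pollens
#'
#' Proposes `l_i + eps * (l_1 - l_2)` with `eps ~ uniform[0, 1]`,
#' clamped to the search bounds. Equal pollens leave `l_i` unchanged.
#'
#' @param l_i Current pollen.
#' @param l_1,l_2 Two pollens drawn from the current population.
#' @param lr_min,lr_max Clamping bounds.
#' @return Candidate learning rate within bounds.
#' @export
self_pollinate <- function(l_i, l_1, l_2, lr_min = 1e-4, lr_max = 0.5) {
  eps <- stats::runif(1)
  clamp(l_i + eps * (l_1 - l_2), lr_min, lr_max)
}

#' Search the learning rate minimizing a fitness function
#'
#' Runs the flower pollination algorithm over the learning-rate interval
#' `[lr_min, lr_max]`: the population is initialized uniformly on the
#' interval (one pollen replaced by `incumbent_lr` when given); at each
#' iteration every pollen proposes a candidate by cross-pollination
#' (with probability `switch_prob`, a Levy-flight move toward the global
#' best) or self-pollination (a random-difference local move), and the
#' candidate replaces the pollen only if its fitness improves (greedy
#' acceptance). The global best is tracked across all evaluations, so
#' the best-fitness trace is nonincreasing and, with an incumbent
#' seeded, the result is never worse than the incumbent.
#'
#' @param fitness Function mapping a learning rate to a loss; must be
#'   deterministic during one call.
#' @param config An [fpa_config()].
#' @param incumbent_lr Optional learning rate seeded into the initial
#'   population.
#' @param seed Optional integer; when given, seeds R's RNG for the call.
#' @return List with `l_best`, `f_best`, and `trace` (best fitness after
#'   each iteration, nonincreasing).
#' @examples
#' res <- optimize_learning_rate(function(l) (l - 0.07)^2,
#'                               fpa_config(n_iterations = 30), seed = 1)
#' res$l_best
#' @export
optimize_learning_rate <- function(fitness, config = fpa_config(),
                                   incumbent_lr = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_pollen
  pollens <- stats::runif(m, config$lr_min, config$lr_max)
  if (!is.null(incumbent_lr)) {
    pollens[1] <- clamp(incumbent_lr, config$lr_min, config$lr_max)
  }
  fits <- vapply(pollens, function(l) as.numeric(fitness(l)), numeric(1))
  if (all(!is.finite(fits))) {
    stop("fitness is non-finite for the whole initial population",
         call. = FALSE)
  }
  fits[!is.finite(fits)] <- Inf
  best_i <- which.min(fits)
  l_best <- pollens[best_i]
  f_best <- fits[best_i]
  trace <- numeric(config$n_iterations)

  for (it in seq_len(config$n_iterations)) {
    for (i in seq_len(m)) {
      P <- stats::runif(1)
      cand <- if (P <= config$switch_prob) {
        cross_pollinate(pollens[i], l_best, config$gamma,
                        config$levy_exponent, config$lr_min, config$lr_max)
      } else {
        js <- sample.int(m, 2L)
        self_pollinate(pollens[i], pollens[js[1]], pollens[js[2]],
                       config$lr_min, config$lr_max)
      }
      f_cand <- as.numeric(fitness(cand))
      if (!is.finite(f_cand)) {
        warning("non-finite fitness at lr = ", signif(cand, 4),
                "; candidate rejected")
        next
      }
      if (f_cand < fits[i]) {
        pollens[i] <- cand
        fits[i] <- f_cand
      }
      if (f_cand < f_best) {
        l_best <- cand
        f_best <- f_cand
      }
    }
    trace[it] <- f_best
  }
  list(l_best = l_best, f_best = f_best, trace = trace)
}
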