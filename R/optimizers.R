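#' Bounded continuous search space
#'
#' @param lower,upper Bound vectors (scalars are recycled to dimension `D`);
#'   `lower < upper` elementwise.
#' @param D Dimension, required when both bounds are scalar.
#' @return An object of class `search_space` with `lower`, `upper`, `D`.
#' @export
search_space <- function(lower, upper, D = NULL) {
  D <- D %||% max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), D)
  upper <- rep_len(as.numeric(upper), D)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("bounds must be finite")
  }
  if (any(lower >= upper)) abort("`lower` must be < `upper` elementwise")
  structure(list(lower = lower, upper = upper, D = D), class = "search_space")
}

#' Optimizer configuration
#'
#' One configuration object covers the four population metaheuristics.
#' Algorithm-specific fields:
#' \describe{
#'   \item{DS}{`p1`, `p2`: mutation-mask rates; when `NULL`, each is drawn
#'     once per run as `0.3 * U(0,1)` (the original differential-search
#'     convention).}
#'   \item{SFLA}{`memeplexes` (z), `local_iters` local updates per memeplex
#'     per shuffle, `Rmax_frac` maximum step as a fraction of the bound
#'     range, `stall_limit` shuffles without improvement before stopping.
#'     `NP` must be a multiple of `memeplexes`.}
#'   \item{WS}{no extras; the control parameter declines linearly 2 to 0
#'     over the run (see [ws_alpha_schedule()]).}
#'   \item{AMO}{`halfwidth`: ring-neighborhood half-width (2 gives the
#'     five-animal neighborhood).}
#' }
#'
#' @param algorithm One of `"DS"`, `"SFLA"`, `"WS"`, `"AMO"`.
#' @param NP Population size (at least 4).
#' @param max_iter Iteration (or shuffle) budget.
#' @param seed RNG seed; runs are bit-reproducible given
#'   `(algorithm, seed, config)`.
#' @param p1,p2,memeplexes,local_iters,Rmax_frac,stall_limit,halfwidth See
#'   above.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("DS", "SFLA", "WS", "AMO"),
                             NP = 20, max_iter = 100, seed = 1,
                             p1 = NULL, p2 = NULL,
                             memeplexes = 4, local_iters = 10,
                             Rmax_frac = 0.2, stall_limit = 50,
                             halfwidth = 2) {
  algorithm <- match.arg(algorithm)
  .fz_check_number(NP, "NP", 4)
  .fz_check_number(max_iter, "max_iter", 1)
  for (p in list(p1, p2)) {
    if (!is.null(p) && (p < 0 || p > 1)) abort("mask rates must be in [0, 1]")
  }
  if (algorithm == "SFLA" && NP %% memeplexes != 0) {
    abort("SFLA requires NP to be a multiple of `memeplexes` (NP = y * z)")
  }
  structure(list(algorithm = algorithm, NP = as.integer(NP),
                 max_iter = as.integer(max_iter), seed = seed,
                 p1 = p1, p2 = p2, memeplexes = as.integer(memeplexes),
                 local_iters = as.integer(local_iters),
                 Rmax_frac = Rmax_frac, stall_limit = as.integer(stall_limit),
                 halfwidth = as.integer(halfwidth)),
            class = "optimizer_config")
}

# Uniform population in bounds; no seeding (callers manage the RNG).
.fz_init_pop <- function(space, NP) {
  matrix(runif(NP * space$D, rep(space$lower, each = NP),
               rep(space$upper, each = NP)), nrow = NP)
}

#' Initialise a uniform population
#'
#' Draws `NP` points uniformly within the bounds, deterministically for a
#' given seed.
#'
#' @param space A [search_space()].
#' @param NP Population size.
#' @param seed RNG seed.
#' @return An `NP x D` matrix.
#' @export
init_population <- function(space, NP, seed = 1) {
  with_seed(as.integer(seed), .fz_init_pop(space, NP))
}

.fz_clamp <- function(pop, space) {
  pop <- pmax(pop, rep(space$lower, each = nrow(pop)))
  pmin(pop, rep(space$upper, each = nrow(pop)))
}

.fz_result <- function(algorithm, pop, fit, trace, evals) {
  i <- which.min(fit)
  structure(list(algorithm = algorithm, best_position = pop[i, ],
                 best_fitness = trace[length(trace)], trace = trace,
                 evaluations = evals), class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result %s: best fitness %.6g after %d evaluations>\n",
              x$algorithm, x$best_fitness, x$evaluations))
  invisible(x)
}

#' @describeIn run_optimizer Tidy the convergence trace.
#' @param x,object An `opt_result`.
#' @param ... Ignored.
#' @export
tidy.opt_result <- function(x, ...) {
  tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}

#' @describeIn run_optimizer One-row run summary.
#' @export
glance.opt_result <- function(x, ...) {
  tibble(algorithm = x$algorithm, best_fitness = x$best_fitness,
         iterations = length(x$trace), evaluations = x$evaluations)
}

#' @describeIn run_optimizer Convergence-trace plot.
#' @export
autoplot.opt_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = object$algorithm)
}

# Shared run prologue: population (optionally seeded with injected rows),
# fitness values, evaluation counter.
.fz_start <- function(fitness, space, config, init) {
  pop <- .fz_init_pop(space, config$NP)
  if (!is.null(init)) {
    init <- matrix(init, ncol = space$D)
    k <- min(nrow(init), config$NP)
    pop[seq_len(k), ] <- .fz_clamp(init[seq_len(k), , drop = FALSE], space)
  }
  fit <- apply(pop, 1, fitness)
  list(pop = pop, fit = fit, evals = config$NP)
}

#' Differential search
#'
#' Population migration toward stopover sites: each individual generates a
#' stopover vector `s = A + scale * (A_r1 - A)` with a gamma-distributed
#' scale modulated by uniform draws, a random subset of coordinates is kept
#' from the parent via the `p1`/`p2` mask rules, out-of-bound trial
#' coordinates are re-drawn uniformly in bounds, and selection is greedy.
#'
#' @param fitness Function mapping a position vector to a scalar to
#'   minimise.
#' @param space A [search_space()].
#' @param config An [optimizer_config()] (the `algorithm` field is ignored
#'   by the individual runners).
#' @param init Optional matrix of rows injected into the initial population.
#' @return An `opt_result`.
#' @export
run_ds <- function(fitness, space, config = optimizer_config("DS"),
                   init = NULL) {
  NP <- config$NP; D <- space$D
  with_seed(as.integer(config$seed), {
    p1 <- config$p1 %||% (0.3 * runif(1))
    p2 <- config$p2 %||% (0.3 * runif(1))
    st <- .fz_start(fitness, space, config, init)
    pop <- st$pop; fit <- st$fit; evals <- st$evals
    trace <- numeric(config$max_iter)
    best <- min(fit)
    for (it in seq_len(config$max_iter)) {
      scale <- rgamma(1, shape = 2 * runif(1) + 1e-12) *
        (runif(1) - runif(1))
      r1 <- vapply(seq_len(NP), function(z) {
        s <- sample.int(NP - 1L, 1L)
        if (s >= z) s + 1L else s
      }, integer(1))
      s <- pop + scale * (pop[r1, , drop = FALSE] - pop)
      keep <- matrix(TRUE, NP, D)  # TRUE = keep the parent coordinate
      if (runif(1) < runif(1)) {
        if (runif(1) < p1) {
          for (z in seq_len(NP)) keep[z, ] <- runif(D) < runif(1)
        } else {
          for (z in seq_len(NP)) keep[z, sample.int(D, 1L)] <- FALSE
        }
      } else {
        for (z in seq_len(NP)) {
          k <- ceiling(p2 * runif(1) * D)
          if (k >= 1) keep[z, sample.int(D, min(k, D))] <- FALSE
        }
      }
      trial <- s
      trial[keep] <- pop[keep]
      out <- trial < rep(space$lower, each = NP) |
        trial > rep(space$upper, each = NP)
      if (any(out)) {
        redraw <- .fz_init_pop(space, NP)
        trial[out] <- redraw[out]
      }
      tfit <- apply(trial, 1, fitness)
      evals <- evals + NP
      better <- tfit <= fit
      pop[better, ] <- trial[better, , drop = FALSE]
      fit[better] <- tfit[better]
      best <- min(best, min(fit))
      trace[it] <- best
    }
    .fz_result("DS", pop, fit, trace, evals)
  })
}

#' Shuffled frog leaping
#'
#' Frogs are ranked by fitness and dealt round-robin into `z` memeplexes
#' (rank 1 to memeplex 1, rank 2 to memeplex 2, ...). Within each memeplex
#' the worst frog steps toward the memeplex best by a per-coordinate
#' random fraction, the step clamped to `+/- Rmax`; failing improvement it
#' steps toward the global best, and failing that it is replaced by a
#' random position (unconditionally — the censoring that keeps the
#' population diverse). The global best is tracked separately, so the
#' reported trace is still non-increasing. Memeplexes are shuffled each
#' outer iteration; the run stops at the shuffle budget or after
#' `stall_limit` shuffles without improvement.
#'
#' @inheritParams run_ds
#' @return An `opt_result`.
#' @export
run_sfla <- function(fitness, space, config = optimizer_config("SFLA"),
                     init = NULL) {
  NP <- config$NP; z <- config$memeplexes
  if (NP %% z != 0) abort("SFLA requires NP = y * z frogs")
  rmax <- config$Rmax_frac * (space$upper - space$lower)
  with_seed(as.integer(config$seed), {
    st <- .fz_start(fitness, space, config, init)
    pop <- st$pop; fit <- st$fit; evals <- st$evals
    gb_i <- which.min(fit)
    gbest <- pop[gb_i, ]; gfit <- fit[gb_i]
    trace <- numeric(0)
    stall <- 0L
    for (sh in seq_len(config$max_iter)) {
      ord <- order(fit)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      prev <- gfit
      for (k in seq_len(z)) {
        mem <- seq(k, NP, by = z)
        for (li in seq_len(config$local_iters)) {
          b <- mem[which.min(fit[mem])]
          w <- mem[which.max(fit[mem])]
          step <- runif(space$D) * (pop[b, ] - pop[w, ])
          step <- pmax(pmin(step, rmax), -rmax)
          cand <- .fz_clamp(matrix(pop[w, ] + step, 1), space)[1, ]
          cfit <- fitness(cand); evals <- evals + 1L
          if (cfit >= fit[w]) {
            step <- runif(space$D) * (gbest - pop[w, ])
            step <- pmax(pmin(step, rmax), -rmax)
            cand <- .fz_clamp(matrix(pop[w, ] + step, 1), space)[1, ]
            cfit <- fitness(cand); evals <- evals + 1L
          }
          if (cfit >= fit[w]) {
            # both guided moves failed: censor the worst frog
            cand <- .fz_init_pop(space, 1L)[1, ]
            cfit <- fitness(cand); evals <- evals + 1L
          }
          pop[w, ] <- cand
          fit[w] <- cfit
          if (cfit < gfit) {
            gfit <- cfit
            gbest <- cand
          }
        }
      }
      trace <- c(trace, gfit)
      stall <- if (gfit < prev) 0L else stall + 1L
      if (stall >= config$stall_limit) break
    }
    .fz_result("SFLA", rbind(gbest, pop), c(gfit, fit), trace, evals)
  })
}

#' Control-parameter schedule of the wolf search
#'
#' The encircling coefficient declines linearly from 2 at iteration 0 to 0
#' at the final iteration: `alpha(t) = 2 * (1 - t / N)`.
#'
#' @param iteration Iteration index in `0..max_iter`.
#' @param max_iter Total iterations `N`.
#' @return The control parameter value.
#' @export
ws_alpha_schedule <- function(iteration, max_iter) {
  2 * (1 - iteration / max_iter)
}

#' Wolf search (grey-wolf position updates)
#'
#' The three best solutions seen so far lead as alpha, beta and delta.
#' Every agent moves to the mean of three pulls, one per leader:
#' `P_L' = P_L - X * |Y * P_L - P|` with `X = 2 a r1 - a`, `Y = 2 r2` and
#' the control parameter `a` declining linearly 2 to 0. Positions are
#' clamped to bounds; leadership is elitist, so the best-fitness trace
#' never increases.
#'
#' @inheritParams run_ds
#' @return An `opt_result`.
#' @export
run_ws <- function(fitness, space, config = optimizer_config("WS"),
                   init = NULL) {
  NP <- config$NP; D <- space$D
  if (NP < 3) abort("wolf search needs NP >= 3")
  with_seed(as.integer(config$seed), {
    st <- .fz_start(fitness, space, config, init)
    pop <- st$pop; fit <- st$fit; evals <- st$evals
    ord <- order(fit)
    leaders <- pop[ord[1:3], , drop = FALSE]
    lfit <- fit[ord[1:3]]
    trace <- numeric(config$max_iter)
    for (it in seq_len(config$max_iter)) {
      a <- ws_alpha_schedule(it, config$max_iter)
      newpop <- matrix(0, NP, D)
      for (l in 1:3) {
        r1 <- matrix(runif(NP * D), NP)
        r2 <- matrix(runif(NP * D), NP)
        xl <- 2 * a * r1 - a
        yl <- 2 * r2
        ld <- rep(leaders[l, ], each = NP)
        dv <- abs(yl * ld - pop)
        newpop <- newpop + (ld - xl * dv)
      }
      pop <- .fz_clamp(newpop / 3, space)
      fit <- apply(pop, 1, fitness)
      evals <- evals + NP
      allpos <- rbind(leaders, pop)
      allfit <- c(lfit, fit)
      ord <- order(allfit)
      leaders <- allpos[ord[1:3], , drop = FALSE]
      lfit <- allfit[ord[1:3]]
      trace[it] <- lfit[1]
    }
    .fz_result("WS", rbind(leaders, pop), c(lfit, fit), trace, evals)
  })
}

#' Ring neighborhood of the animal migration process
#'
#' Indices `j - halfwidth .. j + halfwidth` on the population ring (wrapped
#' modulo `NP`); with the default half-width of 2, index 1 in a population
#' of `NP` has the neighborhood `{NP - 1, NP, 1, 2, 3}`.
#'
#' @param j Animal index in `1..NP`.
#' @param NP Population size.
#' @param halfwidth Neighborhood half-width.
#' @return An integer vector of `2 * halfwidth + 1` indices (including `j`).
#' @export
amo_neighborhood <- function(j, NP, halfwidth = 2) {
  as.integer(((j + seq(-halfwidth, halfwidth) - 1) %% NP) + 1)
}

#' Per-rank replacement probabilities of the animal migration update
#'
#' Probability `Pa` from fitness rank: the best individual gets `1 / NP`,
#' the worst gets 1; a coordinate is replaced when a uniform draw exceeds
#' `Pa`.
#'
#' @param fit Numeric fitness vector (smaller is better).
#' @return Numeric vector of probabilities, aligned with `fit`.
#' @export
amo_update_prob <- function(fit) {
  rank(fit, ties.method = "first") / length(fit)
}

#' Animal migration optimization
#'
#' Alternates a migration step — each animal moves toward a randomly chosen
#' member of its ring neighborhood by a Gaussian factor — with a population
#' update in which coordinates are replaced, with rank-dependent
#' probability, by a recombination of a random animal, the best animal and
#' a second random animal. Both phases keep the better of old and new
#' positions (greedy selection) and clamp to bounds.
#'
#' @inheritParams run_ds
#' @return An `opt_result`.
#' @export
run_amo <- function(fitness, space, config = optimizer_config("AMO"),
                    init = NULL) {
  NP <- config$NP; D <- space$D
  if (NP < 5) abort("animal migration needs NP >= 5")
  hw <- config$halfwidth
  with_seed(as.integer(config$seed), {
    st <- .fz_start(fitness, space, config, init)
    pop <- st$pop; fit <- st$fit; evals <- st$evals
    trace <- numeric(config$max_iter)
    best <- min(fit)
    for (it in seq_len(config$max_iter)) {
      # migration with ring neighborhood
      nb <- vapply(seq_len(NP), function(j) {
        idx <- amo_neighborhood(j, NP, hw)
        idx[sample.int(length(idx), 1L)]
      }, integer(1))
      delta <- rnorm(NP)
      cand <- pop + delta * (pop[nb, , drop = FALSE] - pop)
      cand <- .fz_clamp(cand, space)
      cfit <- apply(cand, 1, fitness)
      evals <- evals + NP
      imp <- cfit <= fit
      pop[imp, ] <- cand[imp, , drop = FALSE]
      fit[imp] <- cfit[imp]
      # population update with rank-based replacement probability
      pa <- amo_update_prob(fit)
      bi <- which.min(fit)
      cand <- pop
      for (j in seq_len(NP)) {
        rr <- sample(setdiff(seq_len(NP), j), 2L)
        repl <- runif(D) > pa[j]
        if (any(repl)) {
          mix <- pop[rr[1], ] + runif(D) * (pop[bi, ] - pop[j, ]) +
            runif(D) * (pop[rr[2], ] - pop[j, ])
          cand[j, repl] <- mix[repl]
        }
      }
      cand <- .fz_clamp(cand, space)
      cfit <- apply(cand, 1, fitness)
      evals <- evals + NP
      imp <- cfit <= fit
      pop[imp, ] <- cand[imp, , drop = FALSE]
      fit[imp] <- cfit[imp]
      best <- min(best, min(fit))
      trace[it] <- best
    }
    .fz_result("AMO", pop, fit, trace, evals)
  })
}

#' Run one of the four optimizers
#'
#' Dispatches on `config$algorithm` to [run_ds()], [run_sfla()],
#' [run_ws()] or [run_amo()].
#'
#' @inheritParams run_ds
#' @return An `opt_result`: `best_position`, `best_fitness`, per-iteration
#'   best-fitness `trace` (non-increasing) and the number of fitness
#'   `evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- run_optimizer(sphere, search_space(-1, 1, D = 3),
#'                      optimizer_config("WS", max_iter = 50))
#' glance(res)
#' @export
run_optimizer <- function(fitness, space, config, init = NULL) {
  if (!inherits(config, "optimizer_config")) {
    abort("`config` must be an optimizer_config")
  }
  switch(config$algorithm,
         DS = run_ds(fitness, space, config, init),
         SFLA = run_sfla(fitness, space, config, init),
         WS = run_ws(fitness, space, config, init),
         AMO = run_amo(fitness, space, config, init))
}

#' Vector-quantization fitness over a value stream
#'
#' The objective used to compress a code-word value stream toward a
#' singleton pattern: for a candidate representative vector `x`,
#' `fitness(x) = mean_i min_j (v_i - x_j)^2` over the stream values `v`.
#' Zero iff every stream value coincides with some representative.
#'
#' @param values Numeric stream values.
#' @return A function of a numeric vector returning the mean squared
#'   quantization error.
#' @export
quantization_fitness <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0) abort("`values` must be non-empty")
  function(x) {
    xs <- sort(x)
    i <- findInterval(v, xs)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(xs))
    mean(pmin((v - xs[lo])^2, (v - xs[hi])^2))
  }
}

#' Optimize a patient's code-word stream
#'
#' Minimises the quantization fitness of the full value stream over
#' `[0, value_max]^L`, seeding the population with the reduced
#' (deduplicated, fixed-length) value vector so the optimum can only
#' improve on it. Returns the optimizer result with the length-`L`
#' representative vector as `best_position`.
#'
#' @param words Code-word tibble ([fuzzy_encode()] rows for one subject), a
#'   character vector of words, or a numeric value stream.
#' @param config An [optimizer_config()].
#' @param L Representative-vector length (default 375).
#' @param value_max Upper bound of the value scale (the all-`E` letter
#'   weight, 0.516129).
#' @return An `opt_result` whose `best_position` has length `L`.
#' @export
optimize_stream <- function(words, config = optimizer_config("WS"),
                            L = 375, value_max = 0.516129) {
  if (is.data.frame(words)) words <- words$letters
  if (length(words) == 0) abort("the code-word stream is empty")
  if (is.character(words)) {
    values <- codeword_value(words)
    seedvec <- reduce_stream(words, L)
  } else {
    values <- as.numeric(words)
    seedvec <- values[((seq_len(L) - 1) %% length(values)) + 1]
  }
  space <- search_space(0, value_max, D = L)
  run_optimizer(quantization_fitness(values), space, config,
                init = matrix(seedvec, nrow = 1))
}
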