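# Binary Artificial Bee Colony optimizer.
#
# A food source is a binary selection vector over features; its fitness
# is cross-validated classifier accuracy on the masked feature table.
# Employed bees propose a candidate near each source and replace it
# greedily; onlooker bees revisit sources with fitness-proportional
# probability; scout bees re-randomize sources whose abandonment counter
# exceeds the limit. The binary update keeps positions where the source
# and its neighbor agree and re-randomizes disagreeing positions.

#' ABC run configuration
#'
#' @param n_sources number of food sources (= employed bees), >= 2.
#' @param limit abandonment threshold: a source is re-randomized when its
#'   counter of consecutive non-improvements exceeds `limit` (strictly).
#' @param max_iter iteration cap (one iteration = employed + onlooker +
#'   scout phase).
#' @param seed integer seed; the whole run is reproducible from it.
#' @return An `abc_config` list.
#' @export
abc_config <- function(n_sources = 20L, limit = 10L, max_iter = 50L, seed = 1L) {
  n_sources <- as.integer(n_sources)
  limit <- as.integer(limit)
  max_iter <- as.integer(max_iter)
  if (n_sources < 2L) stop("`n_sources` must be >= 2")
  if (limit < 1L) stop("`limit` must be >= 1")
  if (max_iter < 0L) stop("`max_iter` must be >= 0")
  structure(list(n_sources = n_sources, limit = limit, max_iter = max_iter,
                 seed = as.integer(seed)),
            class = "abc_config")
}

#' Initialize food sources
#'
#' Each bit is an independent fair 0/1 draw; all-zero vectors are
#' re-drawn (an empty feature selection is unclassifiable). Every source
#' is evaluated once.
#'
#' @param cfg an [abc_config()]; its seed is NOT applied here (callers
#'   like [run_abc()] seed once for the whole run).
#' @param d selection-vector length.
#' @param fitness function taking a 0/1 vector and returning a fitness
#'   value in `[0, 1]`.
#' @return List of food sources: each has `bits`, `fitness`, `ac`
#'   (abandonment counter).
#' @export
init_sources <- function(cfg, d, fitness) {
  lapply(seq_len(cfg$n_sources), function(i) {
    repeat {
      bits <- as.integer(runif(d) < 0.5)
      if (any(bits == 1L)) break
    }
    list(bits = bits, fitness = fitness(bits), ac = 0L)
  })
}

#' Binary candidate solution near a current source
#'
#' Positions where `bits` and `neighbor` agree are kept; each disagreeing
#' position is re-drawn: 0 if a uniform draw is <= 0.5, else 1. From
#' current `{0,1,1,0}` and neighbor `{0,1,0,1}` the candidate is one of
#' `{0,1,1,1}`, `{0,1,1,0}`, `{0,1,0,1}`, `{0,1,0,0}`.
#'
#' @param bits current 0/1 vector.
#' @param neighbor neighboring source's 0/1 vector, same length.
#' @return A 0/1 vector of the same length.
#' @export
abc_candidate <- function(bits, neighbor) {
  if (length(bits) != length(neighbor))
    stop("`bits` and `neighbor` must have equal length")
  out <- as.integer(bits)
  differ <- which(out != as.integer(neighbor))
  if (length(differ) > 0L) {
    phi <- runif(length(differ))
    out[differ] <- ifelse(phi <= 0.5, 0L, 1L)
  }
  out
}

#' Fitness-proportional selection probabilities
#'
#' `P_i = fit_i / sum(fit)`. If every fitness is zero the probabilities
#' degenerate to uniform (reported via `message()`).
#'
#' @param fitness numeric vector of nonnegative fitness values.
#' @return Probability vector summing to 1.
#' @export
selection_probabilities <- function(fitness) {
  if (any(fitness < 0)) stop("fitness values must be nonnegative")
  s <- sum(fitness)
  if (s == 0) {
    message("selection_probabilities: all-zero fitness, using uniform")
    return(rep(1 / length(fitness), length(fitness)))
  }
  fitness / s
}

# Greedy candidate step shared by the employed and onlooker phases:
# propose a candidate near source i (random neighbor k != i), evaluate,
# replace if strictly better (resetting the counter), else count a
# non-improvement.
greedy_step <- function(sources, i, fitness) {
  k <- sample(setdiff(seq_along(sources), i), 1L)
  cand <- abc_candidate(sources[[i]]$bits, sources[[k]]$bits)
  f <- fitness(cand)
  if (f > sources[[i]]$fitness) {
    sources[[i]] <- list(bits = cand, fitness = f, ac = 0L)
  } else {
    sources[[i]]$ac <- sources[[i]]$ac + 1L
  }
  sources
}

#' Employed-bee phase
#'
#' Every source proposes one candidate from a random neighbor and is
#' replaced only on strict fitness improvement.
#'
#' @param sources list of food sources (see [init_sources()]).
#' @param fitness fitness function over 0/1 vectors.
#' @return Updated source list.
#' @export
employed_phase <- function(sources, fitness) {
  for (i in seq_along(sources)) sources <- greedy_step(sources, i, fitness)
  sources
}

#' Onlooker-bee phase
#'
#' Draws `length(sources)` roulette selections proportional to fitness;
#' each selected source undergoes the same greedy candidate step as in
#' the employed phase.
#'
#' @inheritParams employed_phase
#' @return Updated source list.
#' @export
onlooker_phase <- function(sources, fitness) {
  p <- selection_probabilities(vapply(sources, `[[`, 0, "fitness"))
  visits <- sample.int(length(sources), length(sources), replace = TRUE, prob = p)
  for (i in visits) sources <- greedy_step(sources, i, fitness)
  sources
}

#' Scout-bee phase
#'
#' Sources whose abandonment counter strictly exceeds `limit` are
#' replaced by fresh random vectors (evaluated, counter reset). The
#' best-so-far tracker lives outside the sources and is unaffected.
#'
#' @inheritParams employed_phase
#' @param limit abandonment threshold.
#' @param d selection-vector length.
#' @return Updated source list.
#' @export
scout_phase <- function(sources, fitness, limit, d) {
  for (i in seq_along(sources)) {
    if (sources[[i]]$ac > limit) {
      repeat {
        bits <- as.integer(runif(d) < 0.5)
        if (any(bits == 1L)) break
      }
      sources[[i]] <- list(bits = bits, fitness = fitness(bits), ac = 0L)
    }
  }
  sources
}

#' Run the binary ABC optimizer
#'
#' Loops employed -> onlooker -> scout for `max_iter` iterations,
#' tracking the best solution ever evaluated. With `max_iter = 0` the
#' result is the best of the initial population.
#'
#' @param d selection-vector length.
#' @param fitness function mapping a 0/1 vector of length `d` to a
#'   fitness in `[0, 1]`.
#' @param cfg an [abc_config()].
#' @return An `abc_trace`: `best_bits`, `best_fitness`, `curve`
#'   (best-so-far fitness after initialization and after each iteration,
#'   length `max_iter + 1`), `evaluations`, `cache_hits`, `cfg`.
#' @export
run_abc <- function(d, fitness, cfg = abc_config()) {
  set.seed(cfg$seed)
  cache <- new.env(parent = emptyenv())
  stats <- new.env(parent = emptyenv())
  stats$evals <- 0L
  stats$hits <- 0L
  cached_fitness <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) {
      stats$hits <- stats$hits + 1L
      return(cache[[key]])
    }
    stats$evals <- stats$evals + 1L
    val <- if (all(bits == 0L)) 0 else fitness(bits)
    cache[[key]] <- val
    val
  }
  sources <- init_sources(cfg, d, cached_fitness)
  fits <- vapply(sources, `[[`, 0, "fitness")
  best_i <- which.max(fits)
  best_bits <- sources[[best_i]]$bits
  best_fitness <- fits[best_i]
  curve <- numeric(cfg$max_iter + 1L)
  curve[1L] <- best_fitness
  track <- function(sources) {
    fits <- vapply(sources, `[[`, 0, "fitness")
    i <- which.max(fits)
    if (fits[i] > best_fitness) {
      best_fitness <<- fits[i]
      best_bits <<- sources[[i]]$bits
    }
  }
  for (iter in seq_len(cfg$max_iter)) {
    sources <- employed_phase(sources, cached_fitness)
    track(sources)
    sources <- onlooker_phase(sources, cached_fitness)
    track(sources)
    sources <- scout_phase(sources, cached_fitness, cfg$limit, d)
    track(sources)
    curve[iter + 1L] <- best_fitness
  }
  structure(list(best_bits = best_bits, best_fitness = best_fitness,
                 curve = curve, evaluations = stats$evals,
                 cache_hits = stats$hits, cfg = cfg),
            class = "abc_trace")
}

#' @export
print.abc_trace <- function(x, ...) {
  cat(sprintf("<abc_trace> best fitness %.4f with %d/%d features; %d evaluations (%d cache hits)\n",
              x$best_fitness, sum(x$best_bits), length(x$best_bits),
              x$evaluations, x$cache_hits))
  invisible(x)
}

#' ABC feature selection on a feature table
#'
#' Runs [run_abc()] with fitness = k-fold cross-validated accuracy of
#' `spec` on the bit-masked table. The fold assignment is fixed once from
#' `fold_seed`, so fitness is deterministic per bit vector and caching is
#' exact.
#'
#' @param table a `feature_table`.
#' @param spec a [classifier_spec()]; default medium kNN.
#' @param cfg an [abc_config()].
#' @param k cross-validation folds (default 5).
#' @param fold_seed seed for the fold assignment (default `cfg$seed`).
#' @return An `abc_trace` (see [run_abc()]).
#' @export
abc_select <- function(table, spec = classifier_spec("knn", "medium"),
                       cfg = abc_config(), k = 5L, fold_seed = cfg$seed) {
  if (nrow(table$x) == 0L || nlevels(droplevels(table$label)) < 2L)
    stop("feature table must contain both classes")
  folds <- stratified_folds(table$label, k = k, seed = fold_seed)
  fitness <- function(bits) {
    masked <- mask_features(table, bits)
    if (ncol(masked$x) == 0L) return(0)
    cv_accuracy(masked, spec, k = k, folds = folds)
  }
  run_abc(table$space$d, fitness, cfg)
}

#' Write an ABC trace to JSON
#' @param trace an `abc_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path) {
  jsonlite::write_json(
    list(config = unclass(trace$cfg),
         best_bits = paste(trace$best_bits, collapse = ""),
         best_fitness = trace$best_fitness,
         curve = trace$curve,
         evaluations = trace$evaluations,
         cache_hits = trace$cache_hits),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
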