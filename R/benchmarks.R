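## Continuous benchmark functions and the 100-run comparison harness.
##
## All functions are stated in maximisation sense (the classic minimisation
## forms are inverted), following the standard bees-algorithm benchmark
## suite: the search maximises, so a run that solves the problem reports
## the known plateau value (e.g. 3905.93 for De Jong, 0 for Martin & Gaddy
## and Griewank, -0.3979 for Branin).

#' Construct a benchmark function
#'
#' Available functions (all 2-D by default, maximisation sense):
#' * `dejong`: `3905.93 - 100*(x1^2 - x2)^2 - (1 - x1)^2` on
#'   `[-2.048, 2.048]^2`; maximum 3905.93 at (1, 1).
#' * `martin_gaddy`: `-((x1 - x2)^2 + ((x1 + x2 - 10)/3)^2)` on `[0, 10]^2`;
#'   maximum 0 at (5, 5).
#' * `branin`: `-(a*(x2 - b*x1^2 + c*x1 - 6)^2 + 10*(1 - 1/(8*pi))*cos(x1)
#'   + 10)` with `a = 1`, `b = 5.1/(4*pi^2)`, `c = 5/pi`, on
#'   `[-5, 10] x [0, 15]`; maximum -0.397887.
#' * `griewank`: `-(1 + sum(x^2)/4000 - prod(cos(x/sqrt(i))))` on
#'   `[-100, 100]^d`; maximum 0 at the origin.
#'
#' @param name one of `"dejong"`, `"martin_gaddy"`, `"branin"`,
#'   `"griewank"`.
#' @param dimension dimension for `griewank` (default 2); the others are
#'   fixed 2-D.
#' @return an object of class `"benchmark_function"`: list with `name`,
#'   `dimension`, `lower`, `upper`, `evaluate` and `known_optimum`.
#' @export
make_benchmark <- function(name = c("dejong", "martin_gaddy", "branin",
                                    "griewank"),
                           dimension = 2L) {
  if (!is.character(name) || !name[1] %in%
        c("dejong", "martin_gaddy", "branin", "griewank"))
    stop("unknown benchmark '", name[1],
         "'; options: dejong, martin_gaddy, branin, griewank")
  name <- match.arg(name)
  fn <- switch(name,
    dejong = list(
      dimension = 2L, lower = c(-2.048, -2.048), upper = c(2.048, 2.048),
      evaluate = function(x)
        3905.93 - 100 * (x[1]^2 - x[2])^2 - (1 - x[1])^2,
      known_optimum = 3905.93),
    martin_gaddy = list(
      dimension = 2L, lower = c(0, 0), upper = c(10, 10),
      evaluate = function(x)
        -((x[1] - x[2])^2 + ((x[1] + x[2] - 10) / 3)^2),
      known_optimum = 0),
    branin = list(
      dimension = 2L, lower = c(-5, 0), upper = c(10, 15),
      evaluate = function(x) {
        a <- 1; b <- 5.1 / (4 * pi^2); cc <- 5 / pi
        -(a * (x[2] - b * x[1]^2 + cc * x[1] - 6)^2 +
            10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10)
      },
      known_optimum = -0.397887),
    griewank = list(
      dimension = as.integer(dimension),
      lower = rep(-100, dimension), upper = rep(100, dimension),
      evaluate = function(x)
        -(1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x))))),
      known_optimum = 0))
  structure(c(list(name = name), fn), class = "benchmark_function")
}

#' Repeated-run benchmark harness
#'
#' Executes `runs` independent optimizations of a benchmark function with
#' per-run seeds derived from `seed`, and summarises the per-run best
#' objective values by their mean and population standard deviation
#' (divide-by-N), the statistics reported for this kind of study.
#'
#' @param algorithm `"db"` (DE neighbourhood, [run_dbfba()]) or `"ba"`
#'   (classic neighbourhood, [run_ba()]).
#' @param fn a [make_benchmark()] object.
#' @param runs number of independent runs (default 100).
#' @param config an [optimizer_config()]; its `seed` is overridden per run.
#' @param seed master seed from which the per-run seeds are derived.
#' @return an object of class `"trial_summary"`: list with `algorithm`,
#'   `function_name`, `mean`, `std`, `per_run_best`, `seeds`, `runs`.
#' @export
run_trials <- function(algorithm = c("db", "ba"), fn, runs = 100,
                       config = optimizer_config(), seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(fn, "benchmark_function"), runs >= 2)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  runner <- if (algorithm == "db") run_dbfba else run_ba
  best <- vapply(seq_len(runs), function(i) {
    cfg <- config
    cfg$seed <- run_seeds[i]
    runner(fn, cfg)$best_fitness
  }, numeric(1))
  structure(list(algorithm = algorithm, function_name = fn$name,
                 mean = mean(best),
                 std = sqrt(mean((best - mean(best))^2)),
                 per_run_best = best, seeds = run_seeds,
                 runs = as.integer(runs)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("Benchmark trials: ", x$function_name, ", algorithm ",
      toupper(x$algorithm), ", ", x$runs, " runs\n",
      "  mean ", format(x$mean), ", population STD ", format(x$std),
      "\n", sep = "")
  invisible(x)
}
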