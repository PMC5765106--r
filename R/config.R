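#' Load a run configuration
#'
#' Reads a nested key-value (YAML) configuration — or an equivalent in-memory
#' list — validates it against the schema of the chosen mode, fills
#' documented defaults (the published protocol values), and rejects unknown
#' keys by name. Modes: `simulate` (model + initial state + horizon),
#' `equilibria` (model), `classify` (model + winner), `experiment`
#' (experiment protocol or preset).
#'
#' @param x path to a YAML file, or a named list.
#' @return An object of class `run_config` with fields `mode`, `seed`,
#'   `output`, `verbosity`, and the mode's sub-blocks (`model`, `coupling`,
#'   `experiment`, ... as parsed objects).
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L)
    # keep bare `n` / `y` keys literal instead of YAML-1.1 booleans
    yaml::read_yaml(x, handlers = list("bool#yes" = function(v) v,
                                       "bool#no" = function(v) v))
  else if (is.list(x)) x
  else stop("`x` must be a file path or a named list")
  known_top <- c("mode", "seed", "output", "verbosity", "model", "coupling",
                 "state0", "t_end", "winner", "experiment", "preset")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(cfg$mode))
    stop("missing required key: mode")
  mode <- match.arg(cfg$mode, c("simulate", "equilibria", "classify",
                                "experiment"))
  seed <- if (is.null(cfg$seed)) {
    s <- sample.int(2^31 - 1, 1)
    message(sprintf("no seed given; generated seed %d", s))
    s
  } else as.integer(cfg$seed)

  parse_coupling <- function(cc) {
    if (is.null(cc)) return(coupling_params())
    unknown <- setdiff(names(cc), c("nu", "mu", "sigma"))
    if (length(unknown))
      stop(sprintf("unknown coupling key(s): %s",
                   paste(unknown, collapse = ", ")))
    do.call(coupling_params, cc)
  }
  parse_model <- function(mm, coupling) {
    if (is.null(mm)) stop("missing required block: model")
    unknown <- setdiff(names(mm), c("n", "omega", "b", "alpha", "beta",
                                    "gamma", "c"))
    if (length(unknown))
      stop(sprintf("unknown model key(s): %s", paste(unknown, collapse = ", ")))
    for (req in c("n", "omega", "b"))
      if (is.null(mm[[req]]))
        stop(sprintf("missing required model key: %s", req))
    do.call(model_params, c(mm, list(coupling = coupling)))
  }

  out <- list(mode = mode, seed = seed,
              output = if (is.null(cfg$output)) "." else cfg$output,
              verbosity = if (is.null(cfg$verbosity)) 1L
                          else as.integer(cfg$verbosity))
  if (mode %in% c("simulate", "equilibria", "classify")) {
    coupling <- parse_coupling(cfg$coupling)
    out$model <- parse_model(cfg$model, coupling)
    if (mode == "simulate") {
      st <- cfg$state0
      if (is.null(st)) stop("missing required block: state0")
      unknown <- setdiff(names(st), c("phi", "omega0", "a"))
      if (length(unknown))
        stop(sprintf("unknown state0 key(s): %s",
                     paste(unknown, collapse = ", ")))
      out$state0 <- reduced_state(as.numeric(st$phi), st$omega0,
                                  as.numeric(st$a))
      out$t_end <- if (is.null(cfg$t_end)) 100 else as.numeric(cfg$t_end)
    }
    if (mode == "classify")
      out$winner <- if (is.null(cfg$winner)) 1L else as.integer(cfg$winner)
  } else {
    if (!is.null(cfg$preset)) {
      out$experiment <- example_preset(cfg$preset$id, cfg$preset$variant,
                                       n_runs = if (is.null(cfg$preset$n_runs))
                                         1000 else cfg$preset$n_runs,
                                       seed = seed)
    } else {
      ee <- cfg$experiment
      if (is.null(ee)) stop("missing required block: experiment (or preset)")
      known <- setdiff(names(formals(experiment_config)), "coupling")
      unknown <- setdiff(names(ee), c(known, "nu", "mu", "sigma"))
      if (length(unknown))
        stop(sprintf("unknown experiment key(s): %s",
                     paste(unknown, collapse = ", ")))
      coupling <- coupling_params(
        nu = if (is.null(ee$nu)) 20 else ee$nu,
        mu = if (is.null(ee$mu)) 1 else ee$mu,
        sigma = if (is.null(ee$sigma)) 100 else ee$sigma)
      ee <- ee[setdiff(names(ee), c("nu", "mu", "sigma"))]
      ee$coupling <- coupling
      if (is.null(ee$seed)) ee$seed <- seed
      out$experiment <- do.call(experiment_config, ee)
    }
  }
  structure(out, class = "run_config")
}

#' Save a run configuration
#'
#' Writes a `run_config` back to YAML such that `load_config(save_config(x))`
#' reproduces it.
#'
#' @param cfg a `run_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- list(mode = cfg$mode, seed = cfg$seed, output = cfg$output,
            verbosity = cfg$verbosity)
  if (!is.null(cfg$model)) {
    m <- cfg$model
    y$model <- list(n = m$n, omega = m$omega, b = m$b, alpha = m$alpha,
                    beta = m$beta, gamma = m$gamma, c = m$c)
    y$coupling <- unclass(m$coupling)
  }
  if (!is.null(cfg$state0)) {
    n <- cfg$model$n
    y$state0 <- list(phi = as.numeric(cfg$state0[1:n]),
                     omega0 = as.numeric(cfg$state0[[n + 1]]),
                     a = as.numeric(cfg$state0[(n + 2):(2 * n + 1)]))
    y$t_end <- cfg$t_end
  }
  if (!is.null(cfg$winner)) y$winner <- cfg$winner
  if (!is.null(cfg$experiment)) {
    e <- cfg$experiment
    y$experiment <- list(n = e$n, omega_dist = e$omega_dist,
                         phase_range = e$phase_range,
                         theta0_init = e$theta0_init,
                         omega0_init = e$omega0_init, a1_init = e$a1_init,
                         a_other_init = e$a_other_init,
                         nu = e$coupling$nu, mu = e$coupling$mu,
                         sigma = e$coupling$sigma,
                         b = e$b, alpha = e$alpha, beta = e$beta, c = e$c,
                         gamma = e$gamma, T1 = e$T1, T2 = e$T2,
                         H_high = e$H_high, H_low = e$H_low,
                         n_runs = e$n_runs, seed = e$seed)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

.provenance_header <- function(seed, digest_input) {
  ver <- as.character(utils::packageVersion("phasewta"))
  dig <- sum(utf8ToInt(paste(deparse(digest_input), collapse = "")) *
               seq_along(utf8ToInt(paste(deparse(digest_input),
                                         collapse = "")))) %% 1e9
  c(sprintf("# phasewta %s", ver),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("# config-digest: %09d", dig))
}

.write_table <- function(df, path, header) {
  con <- file(path, open = "wb") # binary mode keeps bytes identical
  on.exit(close(con))
  writeLines(header, con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Export results as delimited text
#'
#' Writes the computed artifacts of a session to plain-text tables with a
#' provenance header (package version, seed, config digest). Re-exporting
#' the same bundle produces byte-identical files. Recognized bundle
#' elements: `trajectory` (a `wta_trajectory`), `equilibria` (list of
#' solve results), `tally` (an `outcome_tally`), `regimes` (a
#' [regime_map()] data frame).
#'
#' @param bundle named list of results (non-empty).
#' @param dest destination directory (created if needed).
#' @param seed seed to record in the provenance header.
#' @return character vector of written file paths.
#' @export
export_results <- function(bundle, dest, seed = NULL) {
  if (!is.list(bundle) || length(bundle) == 0)
    stop("`bundle` must be a non-empty list of results")
  if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
  written <- character()
  if (!is.null(bundle$trajectory)) {
    tr <- bundle$trajectory
    stopifnot(inherits(tr, "wta_trajectory"))
    n <- tr$params$n
    df <- data.frame(t = tr$times,
                     tr$phi_wrapped, check.names = FALSE)
    names(df)[1 + seq_len(n)] <- paste0("phi", seq_len(n), "_wrapped")
    unw <- as.data.frame(tr$phi_unwrapped)
    names(unw) <- paste0("phi", seq_len(n), "_unwrapped")
    df <- cbind(df, unw,
                omega0 = tr$states[, "omega0"],
                as.data.frame(trajectory_amplitudes(tr)))
    hdr <- c(.provenance_header(seed, tr$params),
             sprintf("# system: %s, n = %d, b = %g, beta = %g",
                     tr$system, n, tr$params$b, tr$params$beta))
    path <- file.path(dest, "trajectory.tsv")
    written <- c(written, .write_table(df, path, hdr))
  }
  if (!is.null(bundle$equilibria)) {
    recs <- lapply(bundle$equilibria, function(r) {
      eq <- r$equilibrium; st <- r$stability
      ev <- st$eigenvalues
      data.frame(label = eq$label,
                 residual = eq$residual,
                 classification = st$classification,
                 coords = paste(signif(as.numeric(eq$coords), 12),
                                collapse = ","),
                 eigen_re = paste(signif(Re(ev), 12), collapse = ","),
                 eigen_im = paste(signif(Im(ev), 12), collapse = ","))
    })
    df <- do.call(rbind, recs)
    path <- file.path(dest, "equilibria.tsv")
    written <- c(written,
                 .write_table(df, path, .provenance_header(seed, df$label)))
  }
  if (!is.null(bundle$tally)) {
    ta <- bundle$tally
    stopifnot(inherits(ta, "outcome_tally"))
    summ <- data.frame(outcome = names(ta$counts),
                       count = as.integer(ta$counts),
                       fraction = as.numeric(ta$fractions),
                       se = as.numeric(ta$se))
    hdr <- c(.provenance_header(ta$config$seed, ta$config),
             sprintf("# n_runs: %d", ta$config$n_runs))
    written <- c(written,
                 .write_table(summ, file.path(dest, "tally_summary.tsv"), hdr),
                 .write_table(ta$runs, file.path(dest, "tally_runs.tsv"), hdr))
  }
  if (!is.null(bundle$regimes)) {
    written <- c(written,
                 .write_table(bundle$regimes, file.path(dest, "regime_map.tsv"),
                              .provenance_header(seed, dim(bundle$regimes))))
  }
  if (!length(written))
    stop("bundle contained no recognized result element")
  written
}
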