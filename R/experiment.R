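#' Read a flat experiment configuration file
#'
#' Plain-text `key = value` lines grouped under `[section]` headers
#' (sections `network`, `model`, `simulation`, `output`); `#` starts a
#' comment.  Keys become `section.key` entries of the returned list, with
#' numeric-looking values converted.  Unknown keys are rejected by
#' [run_experiment()].
#'
#' @param path Config file path.
#' @return Named list of class `nvm_config`; attribute `hash` holds the
#'   md5 of the file contents.
#' @export
read_config <- function(path) {
  raw <- readLines(path)
  lines <- trimws(sub("#.*$", "", raw))
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(strsplit(val, "[,[:space:]]+")[[1]]))
      if (!anyNA(num)) val <- num
      out[[paste0(section, ".", key)]] <- val
    } else {
      stop("malformed config line: ", ln)
    }
  }
  attr(out, "hash") <- unname(tools::md5sum(path))
  class(out) <- "nvm_config"
  out
}

known_config_keys <- c(
  "network.kind", "network.N", "network.mean_degree", "network.m",
  "network.k1", "network.k2", "network.k", "network.side",
  "network.n_graphs", "network.seed",
  "model.a", "model.a_grid", "model.h",
  "simulation.t_max", "simulation.sample_interval", "simulation.n_real",
  "simulation.transient", "simulation.seed",
  "output.dir", "output.prefix"
)

#' Run a full scan experiment from a configuration
#'
#' Generates the network ensemble, simulates the model over the configured
#' noise value(s), estimates the stationary observables, evaluates the
#' annealed theory at the ensemble-averaged empirical degree moments, and
#' writes a scan CSV, a theory/summary JSON and a reproducibility log to
#' the output directory.  Outputs are a pure function of the configuration
#' (all seeds explicit), and every file carries the config hash.
#'
#' @param config Path to a config file or an `nvm_config` list.
#' @return Invisibly, a list with the `scan` tibble, the theory record and
#'   the written file paths.
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "nvm_config")) config else read_config(config)
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown)) {
    stop("invalid config keys: ", paste(unknown, collapse = ", "))
  }
  need <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) cfg[[key]] else
      if (!is.null(default)) default else stop("missing config key: ", key)
  }
  kind <- need("network.kind")
  N <- as.integer(need("network.N"))
  n_graphs <- as.integer(need("network.n_graphs", 1))
  gseed <- as.integer(need("network.seed", 1))
  h <- need("model.h", 1)
  a_grid <- sort(unique(c(cfg[["model.a"]], cfg[["model.a_grid"]])))
  if (length(a_grid) == 0) stop("missing config key: model.a or model.a_grid")
  t_max <- need("simulation.t_max")
  dt <- need("simulation.sample_interval", 1)
  n_real <- as.integer(need("simulation.n_real", 1))
  transient <- need("simulation.transient", N)
  if (t_max <= transient + dt) {
    stop("simulation.t_max must exceed the transient (", transient,
         ") by at least one sample interval; the averaging window is empty")
  }
  sseed <- as.integer(need("simulation.seed", 1))
  outdir <- need("output.dir", ".")
  prefix <- need("output.prefix", "nvm")

  ens_args <- list(kind = kind, N = N, n_graphs = n_graphs, seed = gseed)
  for (k in c("mean_degree", "m", "k1", "k2", "k", "side")) {
    if (!is.null(cfg[[paste0("network.", k)]])) {
      ens_args[[k]] <- cfg[[paste0("network.", k)]]
    }
  }
  ens <- do.call(make_ensemble, ens_args)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, paste0(prefix, c("_scan.csv", "_theory.json",
                                              "_log.txt")))
  on_fail <- function(e) {
    unlink(paths[file.exists(paths)])
    stop(e)
  }
  tryCatch({
    scan <- scan_variance(ens$graphs, h = h, a_grid = a_grid, t_max = t_max,
                          n_real = n_real, transient = transient,
                          sample_interval = dt, seed = sseed)
    d <- ens$mean_stats
    theory <- lapply(a_grid, function(a) {
      th <- nvm_theory(N, a, h, d)
      th$acf <- NULL
      unclass(th)
    })
    hash <- attr(cfg, "hash")
    scan_out <- dplyr::mutate(scan, config_hash = hash %||% NA_character_)
    write.csv(as.data.frame(scan_out), paths[1], row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, ensemble = as.list(ens$mean_stats[1, ]),
           a_c_empirical = attr(scan, "a_c_empirical"),
           theory = theory),
      paths[2], auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(c(
      paste("config_hash:", hash),
      paste("package_version:", as.character(utils::packageVersion("noisyvoter"))),
      paste("graph_seed:", gseed), paste("sim_seed:", sseed),
      paste("generated:", "deterministic given config")
    ), paths[3])
    invisible(list(scan = scan, theory = theory, paths = paths))
  }, error = on_fail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
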