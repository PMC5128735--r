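## File formats: models as JSON, protocols as YAML, datasets as CSV with
## header protocol,x,y,weight. Model parameter arrays round-trip bit-exactly
## (17 significant digits).

#' Read and write gating models as JSON
#'
#' The schema is a single object with fields `n_states`, `edges` (array of
#' `[i, j]` pairs, 1-based), `conductance`, `basis` (`kind` plus
#' basis-specific fields), `alpha` (array of per-state rows) and `beta`
#' (array of per-edge rows). Parameter arrays are written with full double
#' precision, so write-then-read reproduces them bit-exactly.
#'
#' @param path File path.
#' @param model A valid `markov_model`.
#' @return `read_model()` returns a `markov_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(n_states = model$n_states,
              edges = lapply(seq_len(nrow(model$edges)),
                             function(i) model$edges[i, ]),
              conductance = model$conductance,
              basis = basis_to_list(model$basis),
              alpha = lapply(seq_len(nrow(model$alpha)),
                             function(i) model$alpha[i, ]),
              beta = lapply(seq_len(nrow(model$beta)),
                            function(i) model$beta[i, ]))
  ## I(17): 17 significant digits round-trip IEEE doubles bit-exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  gf_check(file.exists(path), "gatefit_parse_error",
           sprintf("model file does not exist: %s", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) gf_stop("gatefit_parse_error",
                                              paste0("not valid JSON: ",
                                                     conditionMessage(e))))
  need <- c("n_states", "edges", "conductance", "basis", "alpha", "beta")
  for (f in need) {
    gf_check(!is.null(obj[[f]]), "gatefit_parse_error",
             sprintf("model file missing field $.%s", f))
  }
  to_matrix <- function(x, what) {
    m <- tryCatch(if (is.matrix(x)) x else do.call(rbind, x),
                  error = function(e) NULL)
    gf_check(is.numeric(m) && is.matrix(m), "gatefit_parse_error",
             sprintf("$.%s must be an array of equal-length numeric rows", what))
    m
  }
  tryCatch(
    markov_model(n_states = obj$n_states,
                 edges = to_matrix(obj$edges, "edges"),
                 conductance = obj$conductance,
                 alpha = to_matrix(obj$alpha, "alpha"),
                 beta = to_matrix(obj$beta, "beta"),
                 basis = basis_from_list(as.list(obj$basis))),
    gatefit_invalid_argument = function(e)
      gf_stop("gatefit_parse_error",
              paste0("model file ", path, ": ", conditionMessage(e))))
}

#' Read and write voltage-clamp protocols as YAML
#'
#' A protocol file holds `name`, `holding`, `reversal`, `feature`,
#' `normalization`, `sweep` (list of values) and `steps`, each step with
#' `voltage` (mV or the string `sweep`), `duration` (ms or `sweep`),
#' optional `record` and `dt`.
#'
#' @param path File path.
#' @param prot A [protocol()].
#' @return `read_protocol()` returns a `protocol`; `write_protocol()`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(prot, path) {
  obj <- list(name = prot$name, holding = prot$holding,
              reversal = prot$reversal, feature = prot$feature,
              normalization = prot$normalization,
              sweep = as.list(prot$sweep),
              steps = lapply(prot$steps, function(s) {
                out <- list(voltage = s$voltage, duration = s$duration)
                if (s$record) {
                  out$record <- TRUE
                  out$dt <- s$dt
                }
                out
              }))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  gf_check(file.exists(path), "gatefit_parse_error",
           sprintf("protocol file does not exist: %s", path))
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) gf_stop("gatefit_parse_error",
                                              paste0("not valid YAML: ",
                                                     conditionMessage(e))))
  need <- c("name", "holding", "feature", "sweep", "steps")
  for (f in need) {
    gf_check(!is.null(obj[[f]]), "gatefit_parse_error",
             sprintf("protocol file missing field $.%s", f))
  }
  steps <- lapply(seq_along(obj$steps), function(i) {
    s <- obj$steps[[i]]
    gf_check(!is.null(s$voltage) && !is.null(s$duration), "gatefit_parse_error",
             sprintf("$.steps[%d] needs voltage and duration", i))
    tryCatch(protocol_step(s$voltage, s$duration,
                           record = isTRUE(s$record), dt = s$dt),
             gatefit_invalid_argument = function(e)
               gf_stop("gatefit_parse_error",
                       sprintf("$.steps[%d]: %s", i, conditionMessage(e))))
  })
  tryCatch(
    protocol(name = obj$name, holding = obj$holding, steps = steps,
             sweep = unlist(obj$sweep), feature = obj$feature,
             normalization = if (!is.null(obj$normalization))
               obj$normalization else "none",
             reversal = if (!is.null(obj$reversal)) obj$reversal else 0),
    gatefit_invalid_argument = function(e)
      gf_stop("gatefit_parse_error",
              paste0("protocol file ", path, ": ", conditionMessage(e))))
}

#' Read and write target datasets as CSV
#'
#' Datasets are plain CSV with header `protocol,x,y,weight`: one row per
#' observation, `x` the sweep value (mV, ms, or time for trace features),
#' `y` the observed feature value, `weight` a positive fitting weight.
#'
#' @param path File path.
#' @param dataset Data frame with the four columns above.
#' @return `read_dataset()` returns the validated data frame;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(dataset[, c("protocol", "x", "y", "weight")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  gf_check(file.exists(path), "gatefit_parse_error",
           sprintf("dataset file does not exist: %s", path))
  ds <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protocol", "x", "y", "weight")
  gf_check(all(need %in% names(ds)), "gatefit_parse_error",
           paste0("dataset must have columns ", paste(need, collapse = ",")))
  gf_check(is.numeric(ds$x) && is.numeric(ds$y) && is.numeric(ds$weight),
           "gatefit_parse_error", "x, y and weight must be numeric")
  bad <- which(!is.finite(ds$weight) | ds$weight <= 0)
  gf_check(length(bad) == 0L, "gatefit_parse_error",
           sprintf("row %d: weight must be positive", bad[1L]))
  bad <- which(!is.finite(ds$y))
  gf_check(length(bad) == 0L, "gatefit_parse_error",
           sprintf("row %d: y must be finite", bad[1L]))
  ds[, need]
}

#' Write recorded traces as CSV
#'
#' Flattens the traces attached by `run_protocol(..., keep_traces = TRUE)`
#' into rows of (sweep value, recorded-step index, time, per-state
#' occupancy, conductance, current).
#'
#' @param model The simulated `markov_model` (for the conductance vector).
#' @param prot The simulated [protocol()].
#' @param traces The `"traces"` attribute of a [run_protocol()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(model, prot, traces, path) {
  rows <- list()
  for (si in seq_along(traces)) {
    for (wi in seq_along(traces[[si]])) {
      w <- traces[[si]][[wi]]
      occ <- w$occ
      colnames(occ) <- paste0("state", seq_len(ncol(occ)))
      tt <- (seq_len(nrow(occ)) - 1L) * w$dt
      rows[[length(rows) + 1L]] <- data.frame(
        sweep = prot$sweep[si], step = wi, time = tt, occ,
        conductance = w$g, current = w$g * (w$v - prot$reversal))
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
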