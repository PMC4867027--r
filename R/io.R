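# Readers and writers: response datasets as long-format CSV with a JSON
# sidecar (protocol, parameters, seed, baseline noise), results as versioned
# JSON.  CSV dialect: comma-separated, header row, UTF-8, '.' decimal.

SCHEMA_VERSION <- "1.0"

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a response dataset to CSV (+ JSON sidecar)
#'
#' Long format with columns `trial_id, spike_index, spike_time_ms,
#' amplitude_mV`; the sidecar records the protocol spec, generating
#' parameters (if synthetic), seed and baseline noise.
#'
#' @param dataset a [response_dataset].
#' @param path CSV file path (`.json` sidecar written next to it).
#' @return invisible `path`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "response_dataset"))
  rows <- do.call(rbind, lapply(seq_along(dataset$trials), function(i) {
    tr <- dataset$trials[[i]]
    data.frame(trial_id = i, spike_index = seq_along(tr$times),
               spike_time_ms = tr$times, amplitude_mV = tr$amplitudes)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(schema_version = SCHEMA_VERSION,
               protocol = dataset$protocol,
               sigma_n = dataset$sigma_n,
               seed = dataset$seed)
  if (!is.null(dataset$params))
    meta$params <- params_to_list(dataset$params)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a response dataset from CSV (+ JSON sidecar)
#'
#' Validates alignment (one response per spike) and strictly increasing
#' spike times per trial; a missing sidecar yields defaults with a warning.
#'
#' @param path CSV file path written by [write_dataset()] (or compatible).
#' @return a [response_dataset].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("trial_id", "spike_index", "spike_time_ms", "amplitude_mV")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns: ", paste(need, collapse = ", "))
  trials <- lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$spike_index), ]
    if (any(diff(d$spike_time_ms) <= 0)) {
      bad <- which(diff(d$spike_time_ms) <= 0)[1]
      stop(sprintf(
        "non-monotone spike times in trial %s at row %d",
        d$trial_id[1], bad + 1))
    }
    list(times = d$spike_time_ms, amplitudes = d$amplitude_mV)
  })
  names(trials) <- NULL
  meta <- list(sigma_n = NA_real_, seed = NULL, protocol = NULL,
               params = NULL)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sp,
                                                        simplifyVector = TRUE))
  } else {
    warning("no JSON sidecar found for ", path, "; using defaults")
  }
  params <- if (!is.null(meta$params)) params_from_list(meta$params) else NULL
  response_dataset(trials, protocol = meta$protocol, params = params,
                   sigma_n = if (is.null(meta$sigma_n)) NA_real_
                             else meta$sigma_n,
                   seed = meta$seed)
}

#' Write an analysis result as JSON
#'
#' Serializes fit / FIM / bootstrap results (or any named list of numeric
#' fields) with a schema version; parameter fields use exactly the names
#' `N, q, sigma_q, U, tau_D, tau_F, sigma_n`.  Numbers are written at full
#' precision.
#'
#' @param result a result object (e.g. `em_fit`, `fim_result`) or named list.
#' @param path output JSON path.
#' @param seed optional seed to record (stochastic commands must record one).
#' @return invisible `path`.
#' @export
write_result <- function(result, path, seed = NULL) {
  payload <- result_payload(result)
  payload$schema_version <- SCHEMA_VERSION
  if (!is.null(seed)) payload$seed <- seed
  # digits = I(17): decimal-preserving, doubles round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

result_payload <- function(result) {
  if (inherits(result, "em_fit")) {
    out <- list(kind = "em_fit",
                params = params_to_list(result$params_hat),
                log_likelihood = result$log_likelihood,
                n_iterations = result$n_iterations,
                converged = result$converged,
                diagnostics = result$diagnostics)
    if (!is.null(result$per_N_profile))
      out$per_N_profile <- result$per_N_profile
    return(out)
  }
  if (inherits(result, "fim_result"))
    return(list(kind = "fim",
                parameters = FIM_PARAMS,
                matrix = unname(result$matrix),
                n_mc = result$n_mc, seed = result$seed))
  if (inherits(result, "lsf_result"))
    return(list(kind = "lsf", params_ls = as.list(result$params_ls),
                residual = result$residual))
  if (inherits(result, "bootstrap_result"))
    return(list(kind = "bootstrap", bias = as.list(result$bias),
                sd = as.list(result$sd),
                correlations = unname(result$correlations),
                n_reps = result$n_reps, n_failed = result$n_failed,
                seed = result$seed))
  as.list(result)
}

#' Read a JSON result file
#'
#' @param path JSON path written by [write_result()].
#' @return named list.
#' @export
read_result <- function(path)
  jsonlite::read_json(path, simplifyVector = TRUE)
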