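#' Load a design configuration from YAML
#'
#' Unknown fields are rejected with a field-level message; missing fields fall
#' back to the design defaults of [design_config()]. Prior blocks
#' (`tox_prior`, `eff_prior`) are passed through to their constructors the
#' same way.
#'
#' @param path YAML file; an empty file yields the full default design.
#' @return List with `config` ([design_config()]), `tox_prior`, `eff_prior`.
#' @export
load_config <- function(path) {
  o <- yaml::read_yaml(path)
  if (is.null(o)) o <- list()
  build_config(o)
}

build_config <- function(o) {
  check_fields <- function(given, fn, block, extra = character()) {
    allowed <- c(names(formals(fn)), extra)
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown field(s) in ", block, ": ", paste(bad, collapse = ", "))
    given
  }
  cfg_args <- check_fields(o$design %||% list(), design_config, "design",
                           extra = c("N1", "N2"))
  if (!is.null(cfg_args$N1) || !is.null(cfg_args$N2)) {
    # N1/N2 are derived; accept them only if consistent
    tmp <- do.call(design_config,
                   cfg_args[setdiff(names(cfg_args), c("N1", "N2"))])
    if (!is.null(cfg_args$N1) && cfg_args$N1 != tmp$N1)
      stop("N1 = ", cfg_args$N1, " inconsistent with C1 * m1 = ", tmp$N1)
    if (!is.null(cfg_args$N2) && cfg_args$N2 != tmp$N2)
      stop("N2 = ", cfg_args$N2, " inconsistent with n2 + C2 * m2 = ", tmp$N2)
    cfg_args <- cfg_args[setdiff(names(cfg_args), c("N1", "N2"))]
  }
  list(config = do.call(design_config, cfg_args),
       tox_prior = do.call(tox_prior,
                           check_fields(o$tox_prior %||% list(), tox_prior,
                                        "tox_prior")),
       eff_prior = do.call(eff_prior,
                           check_fields(o$eff_prior %||% list(), eff_prior,
                                        "eff_prior")))
}

#' Save a design configuration to YAML
#'
#' @param config A [design_config()].
#' @param path Output file.
#' @param tox_prior_spec,eff_prior_spec Optional prior blocks.
#' @export
save_config <- function(config, path, tox_prior_spec = NULL,
                        eff_prior_spec = NULL) {
  o <- list(design = config[setdiff(names(config), c("N1", "N2"))])
  if (!is.null(tox_prior_spec)) o$tox_prior <- unclass(tox_prior_spec)
  if (!is.null(eff_prior_spec)) o$eff_prior <- unclass(eff_prior_spec)
  yaml::write_yaml(o, path)
  invisible(path)
}

# FNV-1a hash of a serialized object; used for manifest checksums so result
# files can detect truncation/corruption without external dependencies
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keep h as a double in [0, 2^32)
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    # h * 16777619 mod 2^32 in two 16-bit limbs to stay inside 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

canonical_json <- function(payload) {
  ser <- function(p) as.character(jsonlite::toJSON(p, auto_unbox = TRUE,
                                                   digits = NA, na = "null"))
  ser(jsonlite::fromJSON(ser(payload), simplifyVector = TRUE))
}

run_manifest <- function(seed, payload_json) {
  list(package_version = as.character(utils::packageVersion("duocomb")),
       master_seed = seed,
       payload_checksum = fnv1a(payload_json))
}

#' Write / read results with an embedded manifest
#'
#' Losslessly serializes a `trial_result`, `trial_sims` summary, or operating
#' characteristics to JSON together with a manifest (package version, master
#' seed, payload checksum). `read_results()` verifies the checksum and errors
#' on corrupted or truncated files.
#'
#' @param result A `trial_result`, `duocomb_oc`, or any JSON-serializable
#'   list/tibble.
#' @param path Output path.
#' @param seed Master seed recorded in the manifest.
#' @export
write_results <- function(result, path, seed = NA) {
  payload <- serialize_result(result)
  # checksum the canonical (parse/re-serialize) form so that the reader,
  # which only sees the parsed JSON, can recompute it exactly
  out <- list(manifest = run_manifest(seed, canonical_json(payload)),
              class = class(result)[1], payload = payload)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

serialize_result <- function(result) {
  if (inherits(result, "trial_result")) {
    list(decision = result$decision,
         opt_x = result$opt_x, opt_y = result$opt_y,
         max_exceed = result$max_exceed, exch_weight = result$exch_weight,
         n_enrolled = result$n_enrolled, dlt_count = result$dlt_count,
         curve = if (!is.null(result$curve))
           jsonlite::fromJSON(curve_to_json(result$curve)) else NULL,
         records = result$records,
         stage1_log = result$stage1_log)
  } else if (inherits(result, "trial_sims")) {
    list(J = result$J, seed = result$seed,
         truth_label = result$truth$label,
         summary = result$summary)
  } else result
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(o$manifest) || is.null(o$manifest$payload_checksum))
    stop("result file has no manifest: ", path)
  if (!identical(fnv1a(canonical_json(o$payload)), o$manifest$payload_checksum))
    stop("payload checksum mismatch: result file is corrupted or truncated: ",
         path)
  o
}

#' Read / write patient records as CSV
#'
#' Column layout: `patient_id, stage, x_std, y_std, dlt, eff, cohort, alpha`.
#'
#' @param records Patient records tibble (internal layout with `x`, `y`).
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  names(out)[names(out) == "x"] <- "x_std"
  names(out)[names(out) == "y"] <- "y_std"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d)[names(d) == "x_std"] <- "x"
  names(d)[names(d) == "y_std"] <- "y"
  tibble::as_tibble(d)
}
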