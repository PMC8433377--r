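# File formats (CSV with mandatory header, '.' decimal, UTF-8; JSON via
# jsonlite), format validation, and deterministic seed fan-out.
# Frame stacks travel as long-format CSV (frame, time_s, row, col, voltage_V)
# plus a JSON metadata sidecar; calibration and cohort tables as headed CSV;
# rates and reports as JSON.

cohort_csv_names <- c(LAA = "laa_uM", glutamate = "glutamate_uM",
                      choline = "choline_uM", sarcosine = "sarcosine_uM")

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a frame stack to CSV plus JSON sidecar
#'
#' @param stack A `frame_stack`.
#' @param path CSV path; metadata goes to the same path with extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  nf <- nrow(stack$frames)
  nr <- stack$n_rows; ncl <- stack$n_cols
  grid <- expand.grid(row = seq_len(nr), col = seq_len(ncl))
  df <- data.frame(frame = rep(seq_len(nf), times = nr * ncl),
                   time_s = rep(stack$times, times = nr * ncl),
                   row = rep(grid$row, each = nf),
                   col = rep(grid$col, each = nf),
                   voltage_V = as.vector(stack$frames))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- stack$meta
  meta$n_rows <- nr; meta$n_cols <- ncl
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path CSV path (JSON sidecar expected alongside).
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "time_s", "row", "col", "voltage_V")
  if (!all(need %in% names(df)))
    stop("frame-stack CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()
  nr <- meta$n_rows %||% max(df$row)
  ncl <- meta$n_cols %||% max(df$col)
  nf <- max(df$frame)
  frames <- matrix(NA_real_, nf, nr * ncl)
  sens <- (df$col - 1L) * nr + df$row
  frames[cbind(df$frame, sens)] <- df$voltage_V
  times <- df$time_s[match(seq_len(nf), df$frame)]
  structure(list(times = times, frames = frames, n_rows = nr, n_cols = ncl,
                 meta = meta),
            class = "frame_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort table as CSV
#'
#' Columns: `sample_id`, `group`, then one `<metabolite>_uM` column per
#' metabolite (units are part of the schema).
#'
#' @param cohort A cohort data.frame (in-memory metabolite column names).
#' @param path CSV path.
#' @return `path` / the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (m in names(cohort_csv_names))
    if (m %in% names(out))
      names(out)[names(out) == m] <- cohort_csv_names[[m]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  for (m in names(cohort_csv_names))
    if (cohort_csv_names[[m]] %in% names(df))
      names(df)[names(df) == cohort_csv_names[[m]]] <- m
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read a calibration table as CSV
#'
#' Columns: `metabolite`, `concentration_uM`, `rate_mV_per_s`, `replicate`.
#'
#' @param table Calibration data.frame.
#' @param path CSV path.
#' @return `path` / the calibration data.frame.
#' @export
write_calibration <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) utils::read.csv(path)

#' Write / read extracted rates as JSON records
#'
#' Each record carries a channel id, optional `role` (test / negative /
#' posA / posB) and `replicate`, the rate in mV/s, and diagnostics.
#'
#' @param rates A `rate_result` data.frame (or compatible data.frame with a
#'   `rate_mV_per_s` column).
#' @param path JSON path.
#' @return `path` / a data.frame.
#' @export
write_rates <- function(rates, path) {
  jsonlite::write_json(as.data.frame(rates), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path)
  jsonlite::read_json(path, simplifyVector = TRUE)

#' Validate a data file against a named format schema
#'
#' Checks one of the pipeline's file dialects and enumerates all violations
#' instead of failing at the first: required columns (with units in the
#' header), numeric content, and format-specific constraints (e.g. strictly
#' increasing frame times).
#'
#' @param path File path.
#' @param schema One of `"frame_stack"`, `"calibration"`, `"cohort"`,
#'   `"rates"`.
#' @return Character vector of violations; empty if the file is valid.
#' @export
validate_io <- function(path, schema = c("frame_stack", "calibration",
                                         "cohort", "rates")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) return(paste0("file not found: ", path))
  v <- character()
  req <- switch(schema,
                frame_stack = c("frame", "time_s", "row", "col", "voltage_V"),
                calibration = c("metabolite", "concentration_uM",
                                "rate_mV_per_s", "replicate"),
                cohort = c("sample_id", "group"),
                rates = c("channel", "rate_mV_per_s"))
  df <- tryCatch({
    if (schema == "rates") as.data.frame(read_rates(path))
    else utils::read.csv(path)
  }, error = function(e) NULL)
  if (is.null(df)) return(paste0("unreadable as ", schema, ": ", path))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    v <- c(v, paste0("missing column: ", missing_cols))
  num_cols <- intersect(names(df),
                        c("time_s", "voltage_V", "concentration_uM",
                          "rate_mV_per_s", unname(cohort_csv_names)))
  for (col in num_cols)
    if (!is.numeric(df[[col]]))
      v <- c(v, paste0("non-numeric column: ", col))
  if (schema == "frame_stack" && all(c("frame", "time_s") %in% names(df))) {
    tt <- df$time_s[match(sort(unique(df$frame)), df$frame)]
    bad <- which(diff(tt) <= 0)
    if (length(bad) > 0)
      v <- c(v, paste0("non-monotone time at frame ", bad[1] + 1L))
  }
  if (schema == "cohort") {
    conc_cols <- intersect(names(df), unname(cohort_csv_names))
    if (length(conc_cols) == 0)
      v <- c(v, "no metabolite concentration (<name>_uM) columns")
    for (col in conc_cols)
      if (is.numeric(df[[col]]) && any(df[[col]] < 0, na.rm = TRUE))
        v <- c(v, paste0("negative concentrations in: ", col))
  }
  v
}

#' Deterministic per-stage seed fan-out
#'
#' Derives an independent integer substream seed for a named pipeline stage
#' from the global seed, so that each stage is individually reproducible and
#' stages are decoupled. The result is a deterministic hash of
#' (stage, global seed) below 2^31.
#'
#' @param stage Stage name (character).
#' @param global_seed Global integer seed.
#' @return Integer seed.
#' @export
seed_for <- function(stage, global_seed) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(global_seed) %% 2147483647) * 10007) %%
               2147483647)
}

#' Write a machine-readable run manifest next to an output artifact
#'
#' @param out_path Artifact the manifest describes.
#' @param subcommand CLI subcommand or stage name.
#' @param args Named list of effective arguments.
#' @param seed Seed used.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(out_path, subcommand, args, seed) {
  man <- list(artifact = basename(out_path), subcommand = subcommand,
              args = args, seed = seed,
              package_version = as.character(utils::packageVersion("metapanel")))
  mp <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mp)
}
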