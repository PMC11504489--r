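# Delimited-text table contracts. All tables are comma-separated UTF-8
# with a header row and dot decimals. Malformed rows are reported with
# their file line number (header = line 1).

read_table_checked <- function(path, numeric_cols, required,
                               anomer_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L)
    stop("no records in ", path, call. = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in intersect(numeric_cols, names(df))) {
    raw <- df[[cl]]
    suppressWarnings(v <- as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & raw != "")
    if (length(bad))
      stop("non-numeric value in column '", cl, "' of ", path,
           " at line ", bad[1] + 1L, ": '", raw[bad[1]], "'",
           call. = FALSE)
    df[[cl]] <- v
  }
  if (!is.null(anomer_col)) {
    bad <- which(!df[[anomer_col]] %in% c("alpha", "beta"))
    if (length(bad))
      stop("unknown anomer label in ", path, " at line ", bad[1] + 1L,
           ": '", df[[anomer_col]][bad[1]], "'", call. = FALSE)
  }
  df
}

#' Read and write CPMG decay tables
#'
#' Columns: `sample_id`, `anomer` (`alpha`/`beta`), `delay_s`,
#' `intensity`. One [decay_curve()] is formed per (sample_id, anomer)
#' group, in file order.
#'
#' @param path file path.
#' @return `read_decay_table()`: a list of [decay_curve()].
#' @export
read_decay_table <- function(path) {
  df <- read_table_checked(path, c("delay_s", "intensity"),
                           c("sample_id", "anomer", "delay_s", "intensity"),
                           anomer_col = "anomer")
  key <- paste(df$sample_id, df$anomer, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g)
    decay_curve(g$delay_s, g$intensity, anomer = g$anomer[1],
                sample_id = g$sample_id[1]))
}

#' @param curves list of [decay_curve()] objects.
#' @rdname read_decay_table
#' @export
write_decay_table <- function(curves, path) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(sample_id = cv$sample_id, anomer = cv$anomer,
               delay_s = cv$delays, intensity = cv$intensities)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write titration tables
#'
#' Columns: `sample` (`titration` or `reference`), `protein_conc_mM`,
#' `ligand_conc_mM`, `anomer`, `r2_obs_s`, `r2_err_s` (optional, may be
#' empty). `reference` rows carry the protein-free free-state rates; a
#' row per anomer is required.
#'
#' @param path file path.
#' @param anomer_fraction_alpha anomeric fraction to attach to the
#'   dataset (not stored in the table).
#' @return `read_titration_table()`: a [titration_dataset()].
#' @export
read_titration_table <- function(path, anomer_fraction_alpha = 0.4) {
  df <- read_table_checked(
    path, c("protein_conc_mM", "ligand_conc_mM", "r2_obs_s", "r2_err_s"),
    c("sample", "protein_conc_mM", "ligand_conc_mM", "anomer", "r2_obs_s"),
    anomer_col = "anomer")
  bad <- which(!df$sample %in% c("titration", "reference"))
  if (length(bad))
    stop("unknown sample kind in ", path, " at line ", bad[1] + 1L,
         ": '", df$sample[bad[1]], "'", call. = FALSE)
  tit <- df[df$sample == "titration", , drop = FALSE]
  ref <- df[df$sample == "reference", , drop = FALSE]
  if (nrow(tit) == 0L) stop("no titration rows in ", path, call. = FALSE)
  if (!all(c("alpha", "beta") %in% ref$anomer))
    stop("reference rows for both anomers required in ", path,
         call. = FALSE)
  rec <- data.frame(ligand_total = tit$ligand_conc_mM,
                    anomer = tit$anomer,
                    r2_obs = tit$r2_obs_s,
                    stringsAsFactors = FALSE)
  if ("r2_err_s" %in% names(tit) && any(is.finite(tit$r2_err_s)))
    rec$r2_err <- tit$r2_err_s
  ds <- titration_dataset(tit$protein_conc_mM[1], rec,
                          stats::setNames(ref$r2_obs_s, ref$anomer),
                          anomer_fraction_alpha)
  ds$reference_total <- ref$ligand_conc_mM[1]
  ds
}

#' @param data a [titration_dataset()].
#' @rdname read_titration_table
#' @export
write_titration_table <- function(data, path) {
  stopifnot(inherits(data, "titration_dataset"))
  rec <- data$records
  ref_total <- if (!is.null(data$reference_total))
    data$reference_total else NA_real_
  df <- rbind(
    data.frame(sample = "titration",
               protein_conc_mM = data$protein_total,
               ligand_conc_mM = rec$ligand_total,
               anomer = rec$anomer,
               r2_obs_s = rec$r2_obs,
               r2_err_s = if (is.null(rec$r2_err)) NA_real_ else rec$r2_err),
    data.frame(sample = "reference",
               protein_conc_mM = 0,
               ligand_conc_mM = ref_total,
               anomer = names(data$reference_rates),
               r2_obs_s = as.numeric(data$reference_rates),
               r2_err_s = NA_real_)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write competition tables
#'
#' Columns: `protein_conc_mM`, `probe_conc_mM`, `competitor_conc_mM`,
#' `anomer` (probe anomer), `r2_obs_s`. The probe concentration must be
#' constant across rows.
#'
#' @param path file path.
#' @param anomer_fraction_alpha anomeric fraction of the probe.
#' @return `read_competition_table()`: a [competition_dataset()].
#' @export
read_competition_table <- function(path, anomer_fraction_alpha = 0.4) {
  df <- read_table_checked(
    path, c("protein_conc_mM", "probe_conc_mM", "competitor_conc_mM",
            "r2_obs_s"),
    c("protein_conc_mM", "probe_conc_mM", "competitor_conc_mM",
      "anomer", "r2_obs_s"),
    anomer_col = "anomer")
  if (length(unique(df$probe_conc_mM)) != 1L)
    stop("probe concentration must be constant in ", path, call. = FALSE)
  competition_dataset(
    df$protein_conc_mM[1], df$probe_conc_mM[1],
    data.frame(competitor_total = df$competitor_conc_mM,
               anomer = df$anomer, r2_obs = df$r2_obs_s,
               stringsAsFactors = FALSE),
    anomer_fraction_alpha)
}

#' @param data a [competition_dataset()].
#' @rdname read_competition_table
#' @export
write_competition_table <- function(data, path) {
  stopifnot(inherits(data, "competition_dataset"))
  rec <- data$records
  df <- data.frame(protein_conc_mM = data$protein_total,
                   probe_conc_mM = data$probe_total,
                   competitor_conc_mM = rec$competitor_total,
                   anomer = rec$anomer,
                   r2_obs_s = rec$r2_obs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write plate tables
#'
#' Columns: `treatment`, `concentration_mM`, `replicate`, `signal`.
#'
#' @param path file path.
#' @param control control treatment label.
#' @return `read_plate_table()`: a [plate_table()].
#' @export
read_plate_table <- function(path, control = "control") {
  df <- read_table_checked(
    path, c("concentration_mM", "replicate", "signal"),
    c("treatment", "concentration_mM", "replicate", "signal"))
  plate_table(data.frame(treatment = df$treatment,
                         concentration = df$concentration_mM,
                         replicate = df$replicate,
                         signal = df$signal,
                         stringsAsFactors = FALSE),
              control = control)
}

#' @param plate a [plate_table()].
#' @rdname read_plate_table
#' @export
write_plate_table <- function(plate, path) {
  stopifnot(inherits(plate, "plate_table"))
  rec <- plate$records
  utils::write.csv(
    data.frame(treatment = rec$treatment,
               concentration_mM = rec$concentration,
               replicate = rec$replicate, signal = rec$signal),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
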