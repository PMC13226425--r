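# Shared delimited-text dialect: tab-separated, '#' comment lines, '.'
# decimal point, UTF-8.  Every writer puts a comment header with the
# package version and (when given) the generating command line and seed,
# so output tables are self-describing and diffable.

igdyn_header <- function(command = NULL, seed = NULL) {
  h <- sprintf("# igdyn %s | %s",
               as.character(utils::packageVersion("igdyn")),
               format(Sys.time(), "%Y-%m-%d"))
  if (!is.null(command)) h <- c(h, paste("# command:", command))
  if (!is.null(seed)) h <- c(h, paste("# seed:", seed))
  h
}

#' Write a data frame in the igdyn table dialect
#'
#' Tab-separated, UTF-8, with a leading `#` comment header recording the
#' package version and optionally the generating command line and seed.
#' Missing values are written as empty fields.
#'
#' @param x data frame.
#' @param path output file path.
#' @param command,seed optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_igdyn_table <- function(x, path, command = NULL, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(igdyn_header(command, seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a table in the igdyn dialect
#'
#' @param path file path; `#` lines are comments, fields tab-separated,
#'   empty fields become `NA`.
#' @return data frame.
#' @export
read_igdyn_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  # only whole comment lines start with '#': a '#' inside a field is data
  # (pseudo-atom wildcards like HG2#)
  lines <- lines[!startsWith(trimws(lines), "#")]
  utils::read.table(text = lines, header = TRUE, sep = "\t",
                    comment.char = "", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a peak-volume decay table
#'
#' Expected columns: `residue_id`, `delay_s`, `volume`, `experiment_tag`
#' (one of `t1`, `t2`, `noe_sat`, `noe_ref`, `noe_sat_rep`, `noe_ref_rep`).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_decay_table <- function(path) {
  x <- read_igdyn_table(path)
  need <- c("residue_id", "delay_s", "volume", "experiment_tag")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("decay table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a per-residue relaxation record table
#'
#' Expected columns: `residue_id`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`,
#' `NOE_err`; individual fields may be empty for unassigned or overlapped
#' residues.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_relaxation_table <- function(path) {
  x <- read_igdyn_table(path)
  need <- c("residue_id", "R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("relaxation table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a distance-restraint table
#'
#' Expected columns: `res1`, `atom1`, `res2`, `atom2`, `upper_A` and
#' optionally `tag` (`IN`, `OUT` or `shared`).  Atom names may carry a
#' trailing `#` pseudo-atom wildcard (methyl/methylene/equivalent-aromatic
#' groups).
#'
#' @param path file path.
#' @return data frame with a `tag` column (filled with `"shared"` when
#'   absent).
#' @export
read_restraint_table <- function(path) {
  x <- read_igdyn_table(path)
  need <- c("res1", "atom1", "res2", "atom2", "upper_A")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("restraint table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(x$tag)) x$tag <- "shared"
  x
}

#' Read a chemical-shift table
#'
#' Expected columns: `residue_number`, `residue_name` (3-letter code),
#' `atom_name`, `ppm`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_shift_table <- function(path) {
  x <- read_igdyn_table(path)
  need <- c("residue_number", "residue_name", "atom_name", "ppm")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("shift table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' Default run configuration
#'
#' Central defaults shared by the command-line interface and the
#' higher-level analysis functions.  Values follow the standard settings
#' for backbone amide 15N relaxation work at 800 MHz: NOE cutoff 0.6 for
#' residues entering the global tumbling fit and a 0.3 Angstrom tolerance
#' for restraint-compatibility classification.
#'
#' @param ... overrides of individual fields.
#' @return named list with fields `field_MHz`, `r_NH`, `delta_sigma`,
#'   `noe_cutoff`, `tolerance_A`, `n_sim`, `confidence`, `seed`,
#'   `verbosity`.
#' @export
igdyn_config <- function(...) {
  cfg <- list(field_MHz = 800.13, r_NH = 1.02, delta_sigma = -160,
              noe_cutoff = 0.6, tolerance_A = 0.3, n_sim = 500,
              confidence = 0.95, seed = 1L, verbosity = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$field_MHz > 0, cfg$r_NH > 0, cfg$noe_cutoff > -1,
            cfg$tolerance_A >= 0, cfg$n_sim >= 1,
            cfg$confidence > 0, cfg$confidence < 1)
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Unknown keys
#' are rejected.  Values are coerced to the type of the corresponding
#' [igdyn_config] default.
#'
#' @param path file path.
#' @return config list as from [igdyn_config].
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  defaults <- igdyn_config()
  overrides <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    overrides[[k]] <- if (is.numeric(defaults[[k]])) as.numeric(vals[i]) else vals[i]
  }
  do.call(igdyn_config, overrides)
}
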