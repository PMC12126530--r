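# File formats, run configuration and provenance.

.num_re <- "^[+-]?(([0-9]+\\.?[0-9]*)|(\\.[0-9]+))([eE][+-]?[0-9]+)?$"

#' Read a typed CSV table with strict validation
#'
#' UTF-8 CSV with a header. Every schema column must be present; numeric
#' cells are validated before conversion and a failure reports the
#' offending row. Locale decimal commas are rejected explicitly.
#'
#' @param path file path.
#' @param schema named character vector mapping column names to types
#'   (\code{"numeric"}, \code{"integer"}, \code{"character"},
#'   \code{"logical"}). Extra columns in the file are kept as character.
#' @return data.frame of typed records (possibly 0 rows).
#' @export
read_table <- function(path, schema) {
  stopifnot(is.character(schema), !is.null(names(schema)))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    x <- trimws(df[[col]])
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      comma <- grepl("^[+-]?[0-9]+,[0-9]+$", x)
      if (any(comma))
        stop(sprintf(
          "column '%s' row %d: decimal commas are not supported ('%s')",
          col, which(comma)[1], x[which(comma)[1]]), call. = FALSE)
      bad <- nzchar(x) & !grepl(.num_re, x) & !(x %in% c("NA", "NaN"))
      if (any(bad))
        stop(sprintf("column '%s' row %d: non-numeric value '%s'",
                     col, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
      df[[col]] <- if (type == "integer") as.integer(x) else as.numeric(x)
    } else if (type == "logical") {
      df[[col]] <- as.logical(x)
    }
  }
  df
}

#' Write a table as CSV (round-trips through \code{\link{read_table}})
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a PDB structure for RDC back-calculation
#'
#' First model only; alternate locations restricted to '' or 'A'; residues
#' keep author numbering. mmCIF input is rejected with an explicit message.
#'
#' @param path PDB file path.
#' @return object of class \code{"structure_model"} with an \code{atoms}
#'   data.frame (\code{elety}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z}, Angstrom).
#' @export
read_structure <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE))
    stop("mmCIF input is not supported; supply a PDB file", call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  structure(list(atoms = at[, c("elety", "resno", "chain", "x", "y", "z")],
                 path = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, residues %d-%d (%s)\n",
              nrow(x$atoms), min(x$atoms$resno), max(x$atoms$resno),
              x$path))
  invisible(x)
}

.config_keys <- c("datasets", "conditions", "seed", "out_dir",
                  "r2_bound_scale", "use_delta_ex", "dex_sigma_floor",
                  "grid", "t_relax")

#' Read and validate a run configuration
#'
#' YAML key-value file naming input tables, per-dataset conditions
#' (\code{jdp_total_uM}, \code{hsc_total_uM}) and module options. Unknown
#' top-level keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return named list; conditions are converted to
#'   \code{\link{titration_condition}} objects (molar).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$conditions)) {
    cfg$conditions <- lapply(cfg$conditions, function(cd) {
      if (!all(c("jdp_total_uM", "hsc_total_uM") %in% names(cd)))
        stop("each condition needs jdp_total_uM and hsc_total_uM",
             call. = FALSE)
      titration_condition(uM_to_M(cd$jdp_total_uM),
                          uM_to_M(cd$hsc_total_uM))
    })
  }
  cfg
}

#' Provenance block for result files
#'
#' @param seed the seed used for the run.
#' @param config_path optional configuration file; its MD5 is recorded.
#' @return list with package version, seed and config hash.
#' @export
provenance <- function(seed, config_path = NULL) {
  list(package = "cpmgbind",
       version = as.character(utils::packageVersion("cpmgbind")),
       seed = seed,
       config_md5 = if (!is.null(config_path))
         unname(tools::md5sum(config_path)) else NA_character_)
}
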