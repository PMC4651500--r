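# Tabular I/O with gas-analyser column conventions, and parameter-set
# configuration files.

#' Gas-analyser column mapping
#'
#' Maps the package's logical variable names to the column headers commonly
#' written by portable gas-exchange instruments. Pass a modified mapping to
#' [read_gas_exchange()] or the fitting functions when your files use other
#' headers.
#'
#' @param an Net photosynthesis column (umol m-2 s-1).
#' @param gs Stomatal conductance to H2O column (mol m-2 s-1).
#' @param ci Intercellular CO2 column (umol mol-1).
#' @param ca Ambient CO2 column (umol mol-1).
#' @param tleaf Leaf temperature column (degC).
#' @param par Irradiance column (umol m-2 s-1).
#' @param d Vapour pressure deficit column (kPa).
#' @param rh Relative humidity column (percent).
#' @param group Optional grouping column (e.g. curve identifier).
#' @return Named character vector mapping logical names to file columns.
#' @export
gx_columns <- function(an = "Photo", gs = "Cond", ci = "Ci", ca = "CO2S",
                       tleaf = "Tleaf", par = "PARi", d = "VpdL",
                       rh = "RH_S", group = NULL) {
  m <- c(an = an, gs = gs, ci = ci, ca = ca, tleaf = tleaf, par = par,
         d = d, rh = rh)
  if (!is.null(group)) m <- c(m, group = group)
  if (anyDuplicated(names(m))) stop("logical names must be unique",
                                    call. = FALSE)
  m
}

#' Read a gas-exchange table
#'
#' Reads a CSV of leaf gas-exchange measurements, renames mapped columns to
#' the package's logical names, and drops rows with non-finite values in the
#' required variables (with a warning stating how many were removed).
#' Columns in the mapping that are absent from the file are ignored unless
#' listed in `required`.
#'
#' @param path Path to a CSV file.
#' @param columns A [gx_columns()] mapping.
#' @param required Logical names that must be present and finite.
#' @return A data frame with logical column names plus any unmapped columns.
#' @export
read_gas_exchange <- function(path, columns = gx_columns(),
                              required = c("an", "ci")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("no rows in ", path, call. = FALSE)
  for (lg in required) {
    col <- columns[[lg]]
    if (is.null(col) || !col %in% names(dat))
      stop("required column '", col, "' (", lg, ") not found in ", path,
           call. = FALSE)
  }
  present <- columns[columns %in% names(dat)]
  names(dat)[match(present, names(dat))] <- names(present)
  ok <- rep(TRUE, nrow(dat))
  for (lg in required) ok <- ok & is.finite(dat[[lg]])
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite required values dropped",
            call. = FALSE)
    dat <- dat[ok, , drop = FALSE]
  }
  if (nrow(dat) == 0L) stop("no usable rows in ", path, call. = FALSE)
  dat
}

#' Write a gas-exchange or results table
#'
#' CSV writer used by the command-line interface. With `precision = NULL`
#' values are written at full precision; otherwise numeric columns are
#' rounded to `precision` significant digits.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param precision Significant digits, or `NULL` for full precision.
#' @export
write_gas_exchange <- function(x, path, precision = NULL) {
  if (!is.null(precision)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = precision)
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a biochemical parameter configuration
#'
#' Parameter sets can be stored as YAML (`.yml`/`.yaml`) or JSON (`.json`)
#' key-value files whose keys are arguments of [biochem_params()].
#'
#' @param path Path to the configuration file.
#' @param params A [biochem_params()] object (for writing).
#' @return `read_biochem_config` returns a [biochem_params()] object.
#' @export
read_biochem_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(biochem_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(biochem_params, vals)
}

#' @rdname read_biochem_config
#' @export
write_biochem_config <- function(params, path) {
  stopifnot(inherits(params, "biochem_params"))
  vals <- unclass(params)
  vals$gm <- if (is.infinite(vals$gm)) NULL else vals$gm
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

# Accept either a raw analyser table or one already using logical names;
# returns a data frame with the requested logical columns (others kept).
.normalize_columns <- function(data, columns, required, defaults = list()) {
  data <- as.data.frame(data)
  for (lg in names(columns)) {
    if (!lg %in% names(data) && columns[[lg]] %in% names(data))
      names(data)[names(data) == columns[[lg]]] <- lg
  }
  for (lg in names(defaults)) {
    if (!lg %in% names(data)) data[[lg]] <- defaults[[lg]]
  }
  miss <- setdiff(required, names(data))
  if (length(miss))
    stop("missing required column(s): ",
         paste(sprintf("%s ('%s')", miss, columns[miss]), collapse = ", "),
         call. = FALSE)
  data
}
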