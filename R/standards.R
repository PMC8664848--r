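#' Regulatory standards tables
#'
#' A standards table holds, for each measured water property, the admissible
#' (normative) concentration range prescribed by a regulation, plus an optional
#' hard physical domain (e.g. pH is confined to \[0, 14\]).  The table drives
#' two things downstream: the upper limits of the measurement warping and the
#' integration bounds of the Probabilistic Substance Quality Index (PSQI).
#' Parameters with no normative range at all (e.g. Ca, K, HCO3 under SanPiN
#' 1.2.3685-21) are kept in the table but marked unregulated and excluded from
#' PSQI.
#'
#' The packaged default (`load_standards()` with no path) reproduces the
#' SanPiN 1.2.3685-21 drinking-water bounds for the 21 properties handled by
#' this package.  The iron (Fe) entry is regulated with an upper bound that is
#' 0.3 mg/L under the strict reading of the norm; pass
#' `overrides = list(Fe = c(NA, 1))` for the permissive 1 mg/L reading.
#'
#' @name standards
NULL

.std_required_cols <- c("name", "unit", "lower", "upper")

.std_parse_num <- function(x, row, col) {
  # empty cells and dash variants mean "no bound"
  x <- trimws(as.character(x))
  if (length(x) == 0 || is.na(x) || x %in% c("", "-", "–", "—", "NA")) {
    return(NA_real_)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop(sprintf("standards row %d: non-numeric %s bound '%s'", row, col, x),
         call. = FALSE)
  }
  v
}

#' Load and validate a regulatory standards table
#'
#' @param path Path to a standards file, or `NULL` for the packaged SanPiN
#'   1.2.3685-21 defaults.  CSV files need a header
#'   `name,unit,lower,upper,hard_lower,hard_upper` (the two hard-domain
#'   columns are optional); YAML files hold a list of records with the same
#'   keys.  Empty cells or `-` mean "no bound".
#' @param format `"auto"` (by file extension), `"csv"` or `"yaml"`.
#' @param overrides Optional named list; each element is a length-2 numeric
#'   `c(lower, upper)` replacing the normative bounds of the named parameter
#'   (`NA` keeps the packaged value).
#' @return A `psqi_standards` data frame with columns `name`, `unit`, `lower`,
#'   `upper`, `hard_lower`, `hard_upper`, `regulated`.  Row order defines the
#'   canonical column order of all downstream measurement matrices.
#' @examples
#' std <- load_standards()
#' sum(std$regulated)        # 18 of 21 parameters carry a normative range
#' effective_bounds(std, "pH")
#' @export
load_standards <- function(path = NULL, format = c("auto", "csv", "yaml"),
                           overrides = NULL) {
  format <- match.arg(format)
  if (is.null(path)) {
    path <- system.file("extdata", "sanpin_1_2_3685_21.csv", package = "psqigeo")
    format <- "csv"
  }
  if (!file.exists(path)) stop("standards file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  raw <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    recs <- yaml::read_yaml(path)
    do.call(rbind, lapply(recs, function(r) {
      as.data.frame(lapply(
        c(name = "name", unit = "unit", lower = "lower", upper = "upper",
          hard_lower = "hard_lower", hard_upper = "hard_upper"),
        function(k) if (is.null(r[[k]])) NA_character_ else as.character(r[[k]])
      ), stringsAsFactors = FALSE)
    }))
  }
  missing_cols <- setdiff(.std_required_cols, names(raw))
  if (length(missing_cols)) {
    stop("standards file misses column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("hard_lower", "hard_upper")) {
    if (is.null(raw[[col]])) raw[[col]] <- NA_character_
  }

  n <- nrow(raw)
  tab <- data.frame(
    name = trimws(raw$name),
    unit = trimws(raw$unit),
    lower = vapply(seq_len(n), function(i) .std_parse_num(raw$lower[i], i, "lower"), 0),
    upper = vapply(seq_len(n), function(i) .std_parse_num(raw$upper[i], i, "upper"), 0),
    hard_lower = vapply(seq_len(n), function(i) .std_parse_num(raw$hard_lower[i], i, "hard_lower"), 0),
    hard_upper = vapply(seq_len(n), function(i) .std_parse_num(raw$hard_upper[i], i, "hard_upper"), 0),
    stringsAsFactors = FALSE
  )

  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("override for unknown parameter: ", nm, call. = FALSE)
      ov <- as.numeric(overrides[[nm]])
      if (length(ov) != 2) stop("override for ", nm, " must be c(lower, upper)", call. = FALSE)
      if (!is.na(ov[1])) tab$lower[i] <- ov[1]
      if (!is.na(ov[2])) tab$upper[i] <- ov[2]
    }
  }

  validate_standards(tab)
}

#' @rdname standards
#' @param tab A candidate standards data frame (see [load_standards()] for the
#'   column contract).
#' @export
validate_standards <- function(tab) {
  stopifnot(is.data.frame(tab), all(.std_required_cols %in% names(tab)))
  if (anyDuplicated(tab$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    lo <- tab$lower[i]; up <- tab$upper[i]
    if (!is.na(lo) && !is.na(up) && lo >= up) {
      stop(sprintf("standards row %d (%s): lower bound %g >= upper bound %g",
                   i, tab$name[i], lo, up), call. = FALSE)
    }
    hl <- tab$hard_lower[i]; hu <- tab$hard_upper[i]
    if (xor(is.na(hl), is.na(hu))) {
      stop(sprintf("standards row %d (%s): hard domain needs both endpoints",
                   i, tab$name[i]), call. = FALSE)
    }
    if (!is.na(hl)) {
      if (hl >= hu) {
        stop(sprintf("standards row %d (%s): degenerate hard domain", i, tab$name[i]),
             call. = FALSE)
      }
      eff_lo <- if (is.na(lo)) hl else lo
      eff_up <- if (is.na(up)) hu else up
      if (eff_lo < hl || eff_up > hu) {
        stop(sprintf("standards row %d (%s): normative range outside hard domain",
                     i, tab$name[i]), call. = FALSE)
      }
    }
  }
  tab$regulated <- !(is.na(tab$lower) & is.na(tab$upper))
  class(tab) <- c("psqi_standards", "data.frame")
  tab
}

#' Effective PSQI integration bounds of a parameter
#'
#' Two-sided normative ranges are used as printed; one-sided "not above the
#' limit" standards get an effective lower bound of 0 (all concentrations are
#' non-negative), so the PSQI integral is always over a finite rectangle.
#' Unregulated parameters are excluded from PSQI altogether.
#'
#' @param standards A `psqi_standards` table.
#' @param parameter A single parameter name, or `NULL` for the full table.
#' @return For one parameter: a numeric `c(lower, upper)`, or the string
#'   `"excluded"` for an unregulated parameter.  For the full table: a data
#'   frame with `name`, `lower`, `upper`, `excluded`.
#' @export
effective_bounds <- function(standards, parameter = NULL) {
  stopifnot(inherits(standards, "psqi_standards"))
  one <- function(i) {
    if (!standards$regulated[i]) return(NULL)
    lo <- standards$lower[i]
    up <- standards$upper[i]
    if (is.na(lo)) lo <- 0
    if (is.na(up)) up <- standards$hard_upper[i]  # regulated implies one bound present
    c(lower = lo, upper = up)
  }
  if (!is.null(parameter)) {
    i <- match(parameter, standards$name)
    if (is.na(i)) stop("unknown parameter: ", parameter, call. = FALSE)
    b <- one(i)
    if (is.null(b)) return("excluded")
    return(b)
  }
  out <- data.frame(
    name = standards$name,
    lower = NA_real_, upper = NA_real_,
    excluded = !standards$regulated,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(standards))) {
    b <- one(i)
    if (!is.null(b)) { out$lower[i] <- b[1]; out$upper[i] <- b[2] }
  }
  out
}

#' @export
print.psqi_standards <- function(x, ...) {
  cat(sprintf("Standards table: %d parameters (%d regulated, %d excluded from PSQI)\n",
              nrow(x), sum(x$regulated), sum(!x$regulated)))
  print.data.frame(x, ...)
  invisible(x)
}
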