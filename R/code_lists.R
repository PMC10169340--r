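# ICD code-list phenotyping: a small pattern grammar over ICD-9-CM (physical
# conditions) and ICD-10 (mental health conditions) codes.
#
# Grammar:
#   * literal        "714.0", "F43.1"        -- exact match
#   * prefix         "427.3x", "491.x"       -- the trailing "x" (optionally
#                    ".x") matches any suffix, including the empty one, so
#                    "427.3x" matches both "427.3" and "427.31"
#   * bare root      "173"                   -- the whole root family
#                    (equivalent to the degenerate range "173-173")
#   * root range     "140-239", "500-505"    -- inclusive on the 3-character
#                    integer root (letter+digits root for ICD-10)
#   * decimal range  "209.40-209.9x"         -- inclusive on the full numeric
#                    code value; a trailing "x" on the upper endpoint extends
#                    it to that endpoint's whole suffix bucket
# A code matches a code list iff it matches at least one include pattern and
# no exclude pattern. Matching ignores case; en dashes are treated as hyphens.

normalize_code <- function(codes) toupper(trimws(as.character(codes)))

icd_root <- function(codes) sub("\\..*$", "", codes)

code_letter <- function(codes) {
  l <- substr(codes, 1L, 1L)
  ifelse(grepl("^[A-Z]", l), l, "")
}

code_numeric <- function(codes) {
  suppressWarnings(as.numeric(sub("^[A-Z]", "", codes)))
}

parse_range_endpoint <- function(e) {
  e <- trimws(e)
  trailing_x <- grepl("X$", e)
  if (trailing_x) e <- sub("\\.?X$", "", e)
  m <- regmatches(e, regexec("^([A-Z]?)([0-9]{1,3})(\\.([0-9]{1,2}))?$", e))[[1]]
  if (length(m) == 0L) return(NULL)
  has_decimal <- nzchar(m[4L]) # m[4] is the dotted decimal part, e.g. ".9"
  list(
    letter = m[2L],
    value = as.numeric(paste0(m[3L], m[4L])),
    has_decimal = has_decimal,
    trailing_x = trailing_x,
    stem = paste0(m[2L], m[3L], m[4L])
  )
}

#' Compile an ICD code pattern into a vectorized predicate
#'
#' Supports the grammar used by diagnosis code lists for chronic-condition
#' phenotyping: literal codes, `"x"`-suffixed prefixes, bare roots, and
#' inclusive ranges over the integer root (or the full decimal value when an
#' endpoint carries decimals). See [matches_code_list()] for how include and
#' exclude patterns combine.
#'
#' @param pattern a single pattern string, e.g. `"427.3x"` or `"140-239"`
#'   (en dashes accepted)
#' @param code_system `"ICD9"` or `"ICD10"`
#' @return a function taking a character vector of codes and returning a
#'   logical vector; classed `"icd_matcher"`
#' @examples
#' m <- parse_code_pattern("427.3x")
#' m(c("427.31", "427.3", "427.9"))
#' @export
parse_code_pattern <- function(pattern, code_system = c("ICD9", "ICD10")) {
  code_system <- match.arg(code_system)
  p <- toupper(gsub("–|—", "-", trimws(as.character(pattern))))
  bad <- function() {
    stop(sprintf("malformed code pattern: '%s'", pattern), call. = FALSE)
  }
  if (length(p) != 1L || !nzchar(p)) bad()

  if (grepl("-", p, fixed = TRUE)) {
    ends <- strsplit(p, "-", fixed = TRUE)[[1L]]
    if (length(ends) != 2L) bad()
    lo <- parse_range_endpoint(ends[1L])
    hi <- parse_range_endpoint(ends[2L])
    if (is.null(lo) || is.null(hi)) bad()
    if (!identical(lo$letter, hi$letter)) bad()
    if (lo$value > hi$value) bad()
    letter <- lo$letter
    if (!lo$has_decimal && !hi$has_decimal) {
      # inclusive range over the integer root
      f <- function(codes) {
        codes <- normalize_code(codes)
        root <- icd_root(codes)
        rv <- code_numeric(root)
        !is.na(rv) & code_letter(root) == letter &
          rv >= lo$value & rv <= hi$value
      }
    } else {
      f <- function(codes) {
        codes <- normalize_code(codes)
        cv <- code_numeric(codes)
        ok <- !is.na(cv) & code_letter(codes) == letter & cv >= lo$value
        upper <- !is.na(cv) & cv <= hi$value
        if (hi$trailing_x) {
          upper <- upper | startsWith(codes, hi$stem)
        }
        ok & upper
      }
    }
  } else if (grepl("X$", p)) {
    stem <- sub("\\.?X$", "", p)
    if (!grepl("^[A-Z]?[0-9]{1,3}(\\.[0-9]{1,2})?$", stem) || !nzchar(stem)) bad()
    if (grepl("\\.", stem)) {
      f <- function(codes) {
        codes <- normalize_code(codes)
        codes == stem | startsWith(codes, stem)
      }
    } else {
      f <- function(codes) {
        codes <- normalize_code(codes)
        codes == stem | startsWith(codes, paste0(stem, "."))
      }
    }
  } else if (grepl("^[A-Z]?[0-9]{1,3}$", p)) {
    # bare root: the whole family, e.g. "173" matches "173" and "173.9"
    f <- function(codes) icd_root(normalize_code(codes)) == p
  } else if (grepl("^[A-Z]?[0-9]{1,3}\\.[0-9]{1,2}$", p)) {
    f <- function(codes) normalize_code(codes) == p
  } else {
    bad()
  }
  structure(f, pattern = pattern, code_system = code_system,
            class = c("icd_matcher", "function"))
}

#' Construct a condition code list
#'
#' @param condition_name machine name of the condition
#' @param include_patterns character vector of include patterns (non-empty)
#' @param exclude_patterns character vector of exclude patterns
#' @param code_system `"ICD9"` or `"ICD10"`
#' @param label human-readable condition name
#' @return an object of class `"code_list"`
#' @export
code_list <- function(condition_name, include_patterns,
                      exclude_patterns = character(),
                      code_system = c("ICD9", "ICD10"),
                      label = condition_name) {
  code_system <- match.arg(code_system)
  include_patterns <- as.character(include_patterns)
  exclude_patterns <- as.character(exclude_patterns %||% character())
  if (length(include_patterns) == 0L) {
    stop("a code list needs at least one include pattern", call. = FALSE)
  }
  structure(
    list(
      condition_name = condition_name,
      label = label,
      code_system = code_system,
      include_patterns = include_patterns,
      exclude_patterns = exclude_patterns,
      include = lapply(include_patterns, parse_code_pattern, code_system = code_system),
      exclude = lapply(exclude_patterns, parse_code_pattern, code_system = code_system)
    ),
    class = "code_list"
  )
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> %s [%s]\n", x$label, x$code_system))
  cat("  include:", paste(x$include_patterns, collapse = ", "), "\n")
  if (length(x$exclude_patterns)) {
    cat("  exclude:", paste(x$exclude_patterns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Match codes against a code list
#'
#' A code matches iff it matches at least one include pattern and no exclude
#' pattern.
#'
#' @param codes character vector of diagnosis codes
#' @param cl a [code_list()]
#' @return logical vector
#' @export
matches_code_list <- function(codes, cl) {
  stopifnot(inherits(cl, "code_list"))
  if (length(codes) == 0L) return(logical(0L))
  inc <- Reduce(`|`, lapply(cl$include, function(m) m(codes)))
  if (length(cl$exclude)) {
    exc <- Reduce(`|`, lapply(cl$exclude, function(m) m(codes)))
    inc & !exc
  } else {
    inc
  }
}

#' Read condition code lists from a YAML resource
#'
#' The packaged default (`inst/extdata/code_lists.yaml`) carries the code
#' lists defining the chronic physical conditions (ICD-9-CM) and mental
#' health conditions (ICD-10) used for phenotyping; it is human-editable.
#'
#' @param path YAML file; defaults to the packaged resource
#' @return named list of [code_list()] objects
#' @export
read_code_lists <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_lists.yaml", package = "temporeg")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    code_list(
      condition_name = nm,
      include_patterns = unlist(spec$include),
      exclude_patterns = unlist(spec$exclude %||% list()),
      code_system = spec$system,
      label = spec$label %||% nm
    )
  })
  names(out) <- names(raw)
  out
}

.temporeg_env <- new.env(parent = emptyenv())

#' Packaged default code lists
#' @return named list of [code_list()] objects
#' @export
default_code_lists <- function() {
  if (is.null(.temporeg_env$code_lists)) {
    .temporeg_env$code_lists <- read_code_lists()
  }
  .temporeg_env$code_lists
}

#' Flag a condition from one patient's diagnosis records
#'
#' A condition is present iff at least one record in the study period matches
#' the code list. Records from a different code system never match.
#'
#' @param records data.frame with columns `code`, `date`, and optionally
#'   `code_system`
#' @param cl a [code_list()]
#' @param period two dates, closed window (default 2016-01-01 .. 2019-12-31)
#' @return `TRUE`/`FALSE`
#' @export
flag_condition <- function(records, cl,
                           period = as.Date(c("2016-01-01", "2019-12-31"))) {
  stopifnot(inherits(cl, "code_list"))
  period <- as_window(period)
  if (is.null(records) || nrow(records) == 0L) return(FALSE)
  keep <- in_window(as.Date(records$date), period)
  if ("code_system" %in% names(records)) {
    keep <- keep & records$code_system == cl$code_system
  }
  if (!any(keep)) return(FALSE)
  any(matches_code_list(records$code[keep], cl))
}

# Expand a code list's include patterns into a deterministic set of concrete
# codes (exclusion-filtered); used by the synthetic generator so diagnosis
# tables carry realistic codes and exercise the matcher end to end.
expand_code_list <- function(cl, max_roots = 24L) {
  out <- unlist(lapply(cl$include_patterns, function(p0) {
    p <- toupper(gsub("–|—", "-", trimws(p0)))
    if (grepl("-", p, fixed = TRUE)) {
      ends <- strsplit(p, "-", fixed = TRUE)[[1L]]
      lo <- parse_range_endpoint(ends[1L])
      hi <- parse_range_endpoint(ends[2L])
      roots <- floor(lo$value):floor(hi$value)
      if (length(roots) > max_roots) {
        roots <- roots[unique(round(seq(1L, length(roots), length.out = max_roots)))]
      }
      roots <- paste0(lo$letter, sprintf("%03d", roots))
      c(paste0(roots, ".0"), paste0(roots, ".9"))
    } else if (grepl("X$", p)) {
      stem <- sub("\\.?X$", "", p)
      if (grepl("\\.", stem)) {
        c(stem, paste0(stem, 0:9))
      } else {
        c(stem, paste0(stem, ".", 0:9))
      }
    } else {
      p
    }
  }))
  out <- unique(out)
  out[matches_code_list(out, cl)]
}

# Concrete-code sampling pools, one per condition, restricted to codes that
# match no OTHER list of the same code system. Real ICD chapters overlap
# (e.g. hypertensive heart disease codes appear in both the hypertension and
# heart-failure lists); the generator avoids the overlap so that each
# emitted code implies exactly one condition and simulated flags stay
# identifiable.
condition_code_pools <- function(code_lists) {
  pools <- lapply(names(code_lists), function(nm) {
    cl <- code_lists[[nm]]
    pool <- expand_code_list(cl)
    others <- code_lists[setdiff(names(code_lists), nm)]
    others <- Filter(function(o) o$code_system == cl$code_system, others)
    for (o in others) pool <- pool[!matches_code_list(pool, o)]
    if (length(pool) == 0L) {
      stop("condition '", nm, "' has no codes unique to its list", call. = FALSE)
    }
    pool
  })
  names(pools) <- names(code_lists)
  pools
}
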