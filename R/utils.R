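# Internal helpers: deterministic seed derivation, scoped RNG, and a minimal
# TOML subset used for run configs and generation sidecars.

# Deterministically fold integers into one seed below 2^31.  The multiplier
# is small enough that every intermediate product is exactly representable
# in a double.
mixSeed <- function(...) {
  parts <- abs(as.numeric(c(...)))
  s <- 104729
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sigmoid <- function(x) stats::plogis(x)

# --- nested weight-tree arithmetic -----------------------------------------

# Apply f elementwise over one or two weight trees (nested lists whose
# leaves are numeric arrays), preserving structure and dim attributes.
wMap <- function(f, a) {
  if (is.list(a)) return(lapply(a, wMap, f = f))
  r <- f(a)
  attributes(r) <- attributes(a)
  r
}

wMap2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    return(mapply(wMap2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  r <- f(a, b)
  attributes(r) <- attributes(a)
  r
}

wSumSq <- function(a) {
  if (is.list(a)) return(sum(vapply(a, wSumSq, numeric(1))))
  sum(a * a)
}

wCount <- function(a) {
  if (is.list(a)) return(sum(vapply(a, wCount, numeric(1))))
  length(a)
}

# --- minimal TOML subset ----------------------------------------------------
# Supports [section] / [[array-of-tables]] headers, `key = value` pairs with
# string, number, boolean and flat-array values.  Sufficient for run configs
# and generation sidecars.

tomlScalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
  if (tok %in% c("true", "false")) return(tok == "true")
  suppressWarnings(num <- as.numeric(tok))
  if (!is.na(num)) return(num)
  tok
}

#' Read a TOML run configuration
#'
#' Parses the flat TOML subset used by this package's run configurations and
#' sidecars: \code{[section]} and \code{[[table]]} headers and
#' \code{key = value} pairs with string, numeric, boolean or flat-array
#' values.
#'
#' @param path file to read.
#' @return nested named list.
#' @export
readTOML <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  isArray <- FALSE
  for (ln in lines) {
    if (grepl("^\\[\\[.*\\]\\]$", ln)) {
      section <- gsub("^\\[\\[|\\]\\]$", "", ln)
      isArray <- TRUE
      out[[section]] <- c(out[[section]], list(list()))
    } else if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      isArray <- FALSE
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (grepl("^\\[.*\\]$", val)) {
        toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
        parsed <- unlist(lapply(toks, tomlScalar))
      } else parsed <- tomlScalar(val)
      if (is.null(section)) {
        out[[key]] <- parsed
      } else if (isArray) {
        i <- length(out[[section]])
        out[[section]][[i]][[key]] <- parsed
      } else {
        out[[section]][[key]] <- parsed
      }
    }
  }
  out
}

tomlFormat <- function(v) {
  if (is.character(v)) v <- sprintf('"%s"', v)
  if (is.logical(v)) v <- tolower(as.character(v))
  if (length(v) > 1) sprintf("[%s]", paste(v, collapse = ", ")) else as.character(v)
}

#' Write a TOML sidecar
#'
#' Inverse of [readTOML()] for the same subset. Top-level scalars become
#' bare keys; named lists become \code{[section]} tables; unnamed lists of
#' named lists become \code{[[table]]} arrays.
#'
#' @param x nested named list. @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTOML <- function(x, path) {
  lines <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.list(v)) {
      lines <- c(lines, sprintf("%s = %s", nm, tomlFormat(v)))
    } else if (length(v) && is.null(names(v))) {
      for (el in v) {
        lines <- c(lines, "", sprintf("[[%s]]", nm))
        for (k in names(el)) lines <- c(lines, sprintf("%s = %s", k, tomlFormat(el[[k]])))
      }
    } else {
      lines <- c(lines, "", sprintf("[%s]", nm))
      for (k in names(v)) lines <- c(lines, sprintf("%s = %s", k, tomlFormat(v[[k]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a dataset manifest
#'
#' Manifests are tab-separated with a header and columns subject_id,
#' cohort_id, timepoint, split, image_path, mask_path.
#'
#' @param path manifest file.
#' @return data.frame.
#' @export
readManifest <- function(path) {
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort_id", "timepoint", "split", "image_path", "mask_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
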