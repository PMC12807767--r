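## Structured haplotype codes: <prefix>:a1c1t1g1[:v1], short TG-only forms
## for non-coding genes, partial-depth forms (a1, a1c1, ...) and the
## regulatory r-form <RegionID>:r1.

level_order <- c(a = 1L, c = 2L, t = 3L, g = 4L)

#' Construct a structured haplotype code
#'
#' Integer 0 at a level means "non-applicable" (non-coding gene, disrupted
#' translation, intronless transcript, absent annotation); NA means the
#' level is not part of the code (partial depth).  The regulatory form
#' carries only \code{r} and is mutually exclusive with a/c/t/g.  U/D
#' integers are carried in the object but never rendered in canonical code
#' strings.
#'
#' @param prefix gene symbol, transcript id or region id.
#' @param a,c,t,g,u,d,r non-negative integers or NA.
#' @param version optional version string (rendered as \code{:v<version>}).
#' @return object of class \code{ACTGCode}.
#' @export
actg_code <- function(prefix, a = NA, c = NA, t = NA, g = NA,
                      u = NA, d = NA, r = NA, version = NULL) {
  num <- function(x) if (is.na(x)) NA_integer_ else as.integer(x)
  a <- num(a); c <- num(c); t <- num(t); g <- num(g)
  u <- num(u); d <- num(d); r <- num(r)
  if (!is.na(r)) {
    if (r < 1L) stop("r must be >= 1")
    if (!all(is.na(c(a, c, t, g)))) stop("r-form excludes a/c/t/g")
  } else {
    vals <- c(a, c, t, g)
    if (all(is.na(vals))) stop("code needs at least one level")
    if (any(vals < 0L, na.rm = TRUE)) stop("negative level id")
  }
  structure(list(prefix = prefix, a = a, c = c, t = t, g = g,
                 u = u, d = d, r = r, version = version),
            class = "ACTGCode")
}

#' Render a haplotype code as text
#'
#' @param code an [actg_code()].
#' @param style \code{"full"} renders every set level; \code{"short"} drops
#'   the leading \code{a0c0} of non-coding genes; \code{"with_version"} is
#'   \code{"full"} plus the trailing \code{:v<version>} field.
#' @return character scalar, e.g. \code{"HBB:a1c1t1g1"}.
#' @export
format_code <- function(code, style = c("full", "short", "with_version")) {
  style <- match.arg(style)
  if (!is.na(code$r)) {
    body <- paste0("r", code$r)
  } else {
    lv <- c(a = code$a, c = code$c, t = code$t, g = code$g)
    if (style == "short" && !is.na(code$a) && !is.na(code$c) &&
        code$a == 0L && code$c == 0L)
      lv <- lv[c("t", "g")]
    lv <- lv[!is.na(lv)]
    body <- paste0(names(lv), lv, collapse = "")
  }
  out <- paste0(code$prefix, ":", body)
  if (style == "with_version" && !is.null(code$version))
    out <- paste0(out, ":v", code$version)
  out
}

#' @export
print.ACTGCode <- function(x, ...) {
  cat(format_code(x, if (is.null(x$version)) "full" else "with_version"),
      "\n")
  invisible(x)
}

#' Parse a haplotype code string
#'
#' Accepts full (\code{HBB:a1c1t1g1}), partial-depth (\code{NM_000518:a1c1}),
#' short TG-only (\code{NR_002819:t1g0}), versioned
#' (\code{HBB:a1c1:v1}) and regulatory (\code{EH38E3212459:r1}) forms.
#' Level letters must appear in a/c/t/g order, each at most once.
#'
#' @param text code string.
#' @return an [actg_code()]; errors report the 1-based position of the
#'   first offending character.
#' @export
parse_code <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  bad <- function(i) stop("malformed code '", text,
                          "': unexpected character at position ", i,
                          call. = FALSE)
  i <- 1L
  while (i <= n && grepl("[A-Za-z0-9_.~-]", chars[i])) i <- i + 1L
  if (i == 1L) bad(1L)
  if (i > n || chars[i] != ":") bad(min(i, n))
  prefix <- substr(text, 1L, i - 1L)
  i <- i + 1L
  if (i > n) bad(n)
  vals <- c(a = NA, c = NA, t = NA, g = NA)
  r <- NA
  if (chars[i] == "r") {
    j <- i + 1L
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    if (j == i + 1L) bad(min(j, n))
    r <- as.integer(substr(text, i + 1L, j - 1L))
    i <- j
  } else {
    last <- 0L
    repeat {
      if (i > n || chars[i] == ":") break
      if (!chars[i] %in% names(level_order)) bad(i)
      lev <- chars[i]
      if (level_order[[lev]] <= last) bad(i)
      last <- level_order[[lev]]
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j == i + 1L) bad(min(j, n))
      vals[[lev]] <- as.integer(substr(text, i + 1L, j - 1L))
      i <- j
    }
    if (all(is.na(vals))) bad(i)
  }
  version <- NULL
  if (i <= n) {
    if (chars[i] != ":") bad(i)
    if (i + 1L > n || chars[i + 1L] != "v") bad(min(i + 1L, n))
    if (i + 2L > n) bad(n)
    vtxt <- substr(text, i + 2L, n)
    if (!grepl("^[0-9A-Za-z._-]+$", vtxt)) bad(i + 2L)
    version <- vtxt
  }
  actg_code(prefix, a = vals[["a"]], c = vals[["c"]], t = vals[["t"]],
            g = vals[["g"]], r = r, version = version)
}
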