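# ICD code sets: parsing of category-stub ranges, prefix matching and the
# built-in catalog of fire/burn/gas code groups used throughout the package.
#
# Matching granularity is the 3-character ICD-10 category (recorded codes
# append subcategory digits, with or without a dot). ICD-9 codes are numeric,
# optionally prefixed with "E" for external-cause codes; numeric N-codes are
# matched on a configurable prefix length (default 3, so the burn range
# 9400-9490 is represented by the stubs 940-949).

#' Normalise an ICD code string
#'
#' Uppercases and removes dots. Idempotent: applying it twice gives the same
#' result as applying it once.
#'
#' @param x character vector of raw codes (e.g. `"T21.2"`, `"x091"`).
#' @return character vector of normalised codes (`"T212"`, `"X091"`).
#' @export
normalize_icd <- function(x) {
  gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

.is_valid_stub <- function(stub, era) {
  if (era == "ICD10") grepl("^[A-Z][0-9]{2}$", stub)
  else grepl("^E?[0-9]{1,4}$", stub)
}

.is_valid_code <- function(code, era) {
  if (era == "ICD10") grepl("^[A-Z][0-9]{2}", code)
  else grepl("^E?[0-9]+$", code)
}

# expand one ICD-10 stub range, e.g. "S00".."T98" spans letters
.expand_icd10 <- function(from, to) {
  l1 <- substr(from, 1, 1); l2 <- substr(to, 1, 1)
  n1 <- as.integer(substr(from, 2, 3)); n2 <- as.integer(substr(to, 2, 3))
  if (l1 > l2 || (l1 == l2 && n1 > n2)) return(NULL)
  letters_seq <- LETTERS[seq(match(l1, LETTERS), match(l2, LETTERS))]
  out <- character(0)
  for (L in letters_seq) {
    lo <- if (L == l1) n1 else 0L
    hi <- if (L == l2) n2 else 99L
    out <- c(out, sprintf("%s%02d", L, lo:hi))
  }
  out
}

.expand_icd9 <- function(from, to) {
  e1 <- startsWith(from, "E"); e2 <- startsWith(to, "E")
  if (e1 != e2) return(NULL)
  f <- sub("^E", "", from); t <- sub("^E", "", to)
  if (nchar(f) != nchar(t)) return(NULL)
  n1 <- as.integer(f); n2 <- as.integer(t)
  if (n1 > n2) return(NULL)
  stubs <- sprintf(paste0("%0", nchar(f), "d"), n1:n2)
  if (e1) paste0("E", stubs) else stubs
}

#' Parse an ICD code-range specification into a code set
#'
#' A specification is a comma-separated list of single category stubs or
#' hyphenated stub ranges, e.g. `"X00-X09,X76,X97,Y26"` (ICD-10) or
#' `"E890-E899"` (ICD-9). Ranges expand to a duplicate-free set of category
#' stubs; ICD-10 ranges may span letters (`"S00-T98"` gives 199 stubs).
#'
#' @param spec character scalar, the range specification.
#' @param era `"ICD10"` or `"ICD9"`.
#' @param name optional set name carried in the result.
#' @return an object of class `code_set`: list with `name`, `era`, `spec`
#'   and `stubs` (sorted unique category stubs).
#' @examples
#' parse_code_range("X00-X09", "ICD10")   # 10 stubs
#' parse_code_range("T20-T32", "ICD10")   # 13 stubs
#' parse_code_range("T58", "ICD10")       # singleton
#' @export
parse_code_range <- function(spec, era = c("ICD10", "ICD9"), name = spec) {
  era <- match.arg(era)
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty code-range specification")
  stubs <- character(0)
  for (tok in tokens) {
    parts <- normalize_icd(strsplit(tok, "-", fixed = TRUE)[[1]])
    if (!length(parts) %in% c(1L, 2L) || !all(.is_valid_stub(parts, era))) {
      stop(sprintf("malformed %s code stub in token '%s'", era, tok))
    }
    expanded <- if (length(parts) == 1L) parts
      else if (era == "ICD10") .expand_icd10(parts[1], parts[2])
      else .expand_icd9(parts[1], parts[2])
    if (is.null(expanded)) {
      stop(sprintf("reversed or incompatible range in token '%s'", tok))
    }
    stubs <- c(stubs, expanded)
  }
  structure(
    list(name = name, era = era, spec = spec, stubs = sort(unique(stubs))),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set '%s' (%s): %d stubs from \"%s\">\n",
              x$name, x$era, length(x$stubs), x$spec))
  invisible(x)
}

#' Category stub of a recorded code
#'
#' First three characters of a normalised ICD-10 code; for ICD-9, the first
#' `icd9_prefix` digits (external-cause codes keep their `E` prefix and use
#' three digits after it).
#'
#' @param code character vector of raw codes.
#' @param era era of the codes (scalar or vector).
#' @param icd9_prefix numeric-prefix length for ICD-9 N-codes.
#' @return character vector of stubs; `NA` for empty/`NA` input.
#' @export
icd_stub <- function(code, era = "ICD10", icd9_prefix = 3L) {
  x <- normalize_icd(code)
  x[!nzchar(x) | is.na(code)] <- NA_character_
  if (length(era) == 1L) era <- rep(era, length(x))
  out <- substr(x, 1L, 3L)
  i9 <- which(era == "ICD9" & !is.na(x))
  if (length(i9)) {
    e <- startsWith(x[i9], "E")
    out[i9] <- ifelse(e, substr(x[i9], 1L, 4L), substr(x[i9], 1L, icd9_prefix))
  }
  out
}

#' Test recorded codes against a code set
#'
#' A code matches when its category stub belongs to the set's expanded
#' stubs. Vectorised over `code`.
#'
#' @param code character vector of raw recorded codes.
#' @param set a `code_set`.
#' @param era era of the recorded codes; must equal `set$era`.
#' @param icd9_prefix prefix length for ICD-9 numeric codes.
#' @return logical vector; `FALSE` for missing/empty codes.
#' @examples
#' burn <- parse_code_range("T20-T32,T95", "ICD10", "BURN_N")
#' code_matches("T21.2", burn)  # TRUE
#' code_matches("T33", burn)    # FALSE
#' @export
code_matches <- function(code, set, era = set$era, icd9_prefix = 3L) {
  stopifnot(inherits(set, "code_set"))
  if (!all(era == set$era)) {
    stop(sprintf("era mismatch: codes are %s but set '%s' is %s",
                 paste(unique(era), collapse = "/"), set$name, set$era))
  }
  stub <- icd_stub(code, era, icd9_prefix)
  !is.na(stub) & stub %in% set$stubs
}

#' Built-in catalog of code sets
#'
#' All code groups the analysis uses: fire-related external causes
#' (X00-X09, X76, X97, Y26; ICD-9 E890-E899), gas-exposure E-code (X47),
#' burn diagnoses (T20-T32 and sequelae T95; ICD-9 940-949 prefixes),
#' combustion gas poisoning diagnoses (T58-T59; ICD-9 986), the unspecific
#' external causes X58-X59, E-code ranges that contradict a fire mechanism
#' (X10-X19, X30-X39, W32-W40, W85-W99), the injury chapter S00-T98
#' (ICD-9 800-999), the era E-code domains (ICD-10 V01-Y89; ICD-9
#' E880-E900) and psychiatric main diagnoses F00-F99.
#'
#' @param icd9_ecode_end upper bound of the ICD-9 E-code domain. The
#'   register documentation gives E880-E900; whether E900 (heat) is
#'   inclusive is ambiguous, so the bound is exposed here (inclusive by
#'   default).
#' @param icd9_injury_range ICD-9 N-code range treated as injury for the
#'   bed-day criteria.
#' @return object of class `code_catalog`: list with one named list of
#'   `code_set`s per era.
#' @export
code_catalog <- function(icd9_ecode_end = "E900",
                         icd9_injury_range = "800-999") {
  mk10 <- function(name, spec) parse_code_range(spec, "ICD10", name)
  mk9  <- function(name, spec) parse_code_range(spec, "ICD9", name)
  structure(list(
    ICD10 = list(
      FIRE_E       = mk10("FIRE_E", "X00-X09,X76,X97,Y26"),
      GAS_E        = mk10("GAS_E", "X47"),
      BURN_N       = mk10("BURN_N", "T20-T32,T95"),
      GAS_N        = mk10("GAS_N", "T58,T59"),
      UNSPECIFIC_E = mk10("UNSPECIFIC_E", "X58,X59"),
      CONTRADICT_E = mk10("CONTRADICT_E", "X10-X19,X30-X39,W32-W40,W85-W99"),
      INJURY_N     = mk10("INJURY_N", "S00-T98"),
      ECODE_DOMAIN = mk10("ECODE_DOMAIN", "V01-Y89"),
      PSYCH_DX     = mk10("PSYCH_DX", "F00-F99")
    ),
    # the unspecific/contradicting E-code audit sets are ICD-10 concepts and
    # have no ICD-9 counterpart here
    ICD9 = list(
      FIRE_E       = mk9("FIRE_E", "E890-E899"),
      BURN_N       = mk9("BURN_N", "940-949"),
      GAS_N        = mk9("GAS_N", "986"),
      INJURY_N     = mk9("INJURY_N", icd9_injury_range),
      ECODE_DOMAIN = mk9("ECODE_DOMAIN", paste0("E880-", icd9_ecode_end)),
      PSYCH_DX     = mk9("PSYCH_DX", "290-319")
    )
  ), class = "code_catalog")
}

#' @export
print.code_catalog <- function(x, ...) {
  for (era in names(x)) {
    cat(era, ":\n", sep = "")
    for (s in x[[era]]) {
      cat(sprintf("  %-12s %s\n", s$name, s$spec))
    }
  }
  invisible(x)
}

#' Fetch a named set from a catalog
#'
#' @param catalog a `code_catalog`.
#' @param name set name, e.g. `"BURN_N"`.
#' @param era `"ICD10"` or `"ICD9"`.
#' @return a `code_set`.
#' @export
catalog_set <- function(catalog, name, era = "ICD10") {
  s <- catalog[[era]][[name]]
  if (is.null(s)) stop(sprintf("code set '%s' (%s) not in catalog", name, era))
  s
}

#' Load code-set overrides from a YAML config file
#'
#' The file maps set names to entries with fields `era` and `spec`; listed
#' sets replace the built-in ones, all others keep their defaults.
#'
#' @param path YAML file path.
#' @param base catalog to override (default the built-in one).
#' @return a `code_catalog`.
#' @export
read_code_config <- function(path, base = code_catalog()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    if (is.null(entry$era) || is.null(entry$spec)) {
      stop(sprintf("config entry '%s' needs fields 'era' and 'spec'", nm))
    }
    base[[entry$era]][[nm]] <- parse_code_range(entry$spec, entry$era, nm)
  }
  base
}

#' Classify the completeness of a single E-code field
#'
#' `MISSING` when absent, `UNSPECIFIC` when the code is one of the
#' uninformative external causes X58-X59 (accidental exposure to other and
#' unspecified factors), `SPECIFIC` otherwise. A present code outside the
#' era's declared E-code domain still counts as SPECIFIC — completeness is
#' about the presence of any external-cause information — but triggers a
#' warning.
#'
#' @param ecode character vector of E-codes; `NA` or `""` means absent.
#' @param era era of the codes (scalar or vector).
#' @param catalog a `code_catalog`.
#' @param warn warn about present codes outside the era's E-code domain.
#' @return factor with levels `MISSING`, `UNSPECIFIC`, `SPECIFIC`.
#' @examples
#' ecode_completeness(c("X00", "X58", NA))
#' @export
ecode_completeness <- function(ecode, era = "ICD10",
                               catalog = code_catalog(), warn = TRUE) {
  n <- length(ecode)
  if (length(era) == 1L) era <- rep(era, n)
  out <- rep("SPECIFIC", n)
  absent <- is.na(ecode) | !nzchar(trimws(as.character(ecode)))
  out[absent] <- "MISSING"
  for (e in unique(era)) {
    i <- which(era == e & !absent)
    if (!length(i)) next
    if (e == "ICD10") {
      unspec <- code_matches(ecode[i], catalog$ICD10$UNSPECIFIC_E)
      out[i[unspec]] <- "UNSPECIFIC"
    }
    dom <- catalog[[e]]$ECODE_DOMAIN
    outside <- !code_matches(ecode[i], dom, era = e)
    if (warn && any(outside)) {
      warning(sprintf(
        "%d present E-code(s) outside the %s E-code domain; treated as SPECIFIC",
        sum(outside), e))
    }
  }
  factor(out, levels = c("MISSING", "UNSPECIFIC", "SPECIFIC"))
}
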