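#' Parse a binary root-colour phenotype code
#'
#' Carrot roots are phenotyped by scoring presence (`1`) or absence (`0`) of
#' purple coloration in four concentric tissues, ordered periderm (skin),
#' cortex, phloem, xylem. The canonical string form is `":bbbb"`, e.g.
#' `":1111"` for a fully purple root and `":1000"` for purple periderm only.
#'
#' @param x A phenotype string, with or without the leading colon.
#' @return An object of class `phenotype_code`: a named logical vector with
#'   elements `periderm`, `cortex`, `phloem`, `xylem`.
#' @examples
#' parse_phenotype(":1101")
#' format(parse_phenotype("1000"))
#' @export
parse_phenotype <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  body <- sub("^:", "", x)
  chars <- strsplit(body, "")[[1]]
  if (length(chars) != 4L) {
    stop("phenotype code must have exactly 4 binary digits, got ",
         length(chars), " in '", x, "'", call. = FALSE)
  }
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad)) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " of phenotype code '", x, "'", call. = FALSE)
  }
  flags <- chars == "1"
  names(flags) <- c("periderm", "cortex", "phloem", "xylem")
  structure(flags, class = "phenotype_code")
}

#' @export
format.phenotype_code <- function(x, ...) {
  paste0(":", paste(as.integer(unclass(x)), collapse = ""))
}

#' @export
print.phenotype_code <- function(x, ...) {
  cat("<phenotype", format(x), ">",
      if (any(x)) paste("purple:", paste(names(x)[x], collapse = ", "))
      else "non-purple", "\n")
  invisible(x)
}

#' Test whether a phenotype code denotes a purple root
#'
#' A sample counts as purple when at least one of the four tissues is scored
#' purple, i.e. any code other than `":0000"`.
#'
#' @param code Character vector of phenotype codes.
#' @return Logical vector.
#' @export
is_purple <- function(code) {
  vapply(code, function(ci) any(unclass(parse_phenotype(ci))), logical(1),
         USE.NAMES = FALSE)
}

#' S.H.E diversity of phenotype categories
#'
#' Computes category richness S, Shannon-Wiener diversity H (natural log) and
#' Shannon evenness E = H / ln(S) from a vector of category counts, the
#' convention used to summarise binary root-colour phenotypic diversity across
#' a germplasm panel. H is computed by [vegan::diversity()].
#'
#' @param counts Named non-negative numeric vector of per-category counts.
#'   At least one count must be positive; zero-count categories are dropped.
#' @return An object of class `she_diversity`: list with elements `S`, `logS`,
#'   `H` and `E` (E is defined as 0 when only one category is present).
#' @examples
#' she_diversity(c(`:1111` = 60, `:1000` = 25, `:0000` = 296))
#' @export
she_diversity <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all category counts are zero", call. = FALSE)
  S <- length(counts)
  H <- unname(vegan::diversity(counts, index = "shannon"))
  E <- if (S > 1L) H / log(S) else 0
  structure(list(S = S, logS = log(S), H = H, E = E),
            class = "she_diversity")
}

#' @export
print.she_diversity <- function(x, ...) {
  cat(sprintf("S.H.E diversity: S = %d, log S = %.4f, H = %.4f, E = %.4f\n",
              x$S, x$logS, x$H, x$E))
  invisible(x)
}
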