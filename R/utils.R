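# Shared helpers: genotype codes, rounding conventions, seeded substreams.

#' Normalize a diploid genotype code
#'
#' Genotypes are allele indices separated by `/` (0 = reference, 1 = first
#' alternate, 2 = second alternate). Phase separators (`|`) are replaced by
#' `/` and allele indices are sorted so that `"1/0"` and `"0/1"` are the same
#' genotype. Any genotype containing a missing allele becomes `"./."`.
#'
#' @param gt character vector of genotype codes.
#' @return character vector of normalized codes.
#' @export
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || any(p == ".") || any(is.na(p)) || any(p == "")) {
      return("./.")
    }
    a <- sort(as.integer(p))
    paste(a, collapse = "/")
  }, character(1))
}

# Integer alleles of a normalized genotype, or NULL when missing.
gt_alleles <- function(gt) {
  if (is.na(gt) || gt == "./.") return(NULL)
  as.integer(strsplit(gt, "/", fixed = TRUE)[[1]])
}

# TRUE when genotype is a/a with a >= 1.
gt_is_hom_var <- function(gt) {
  a <- gt_alleles(gt)
  !is.null(a) && a[1] == a[2] && a[1] >= 1L
}

# TRUE when genotype carries at least one non-reference allele.
gt_is_variant <- function(gt) {
  a <- gt_alleles(gt)
  !is.null(a) && any(a >= 1L)
}

#' Round a percentage to two decimals, half away from zero
#'
#' Base R `round()` rounds half to even; published tables conventionally
#' round half away from zero, so that convention is used for all reported
#' percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with the package's reporting convention
#'
#' @param num numerator count.
#' @param den denominator count; a zero denominator yields `NA` rather than
#'   a division error (0/0 percentages are reported as missing).
#' @return percentage on the 0--100 scale, rounded to two decimals.
#' @export
pct <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den))
}

#' Transition / transversion ratio from substitution counts
#'
#' Transitions are A<->G and C<->T; the remaining four substitution classes
#' are transversions.
#'
#' @param n_transitions,n_transversions substitution counts.
#' @return Ti/Tv ratio (`NA` when there are no transversions).
#' @export
titv_ratio <- function(n_transitions, n_transversions) {
  ifelse(n_transversions == 0, NA_real_, n_transitions / n_transversions)
}

#' Is a single-base substitution a transition?
#'
#' @param ref,alt single reference and alternate bases (vectors recycle).
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  r <- toupper(ref); a <- toupper(alt)
  (r == "A" & a == "G") | (r == "G" & a == "A") |
    (r == "C" & a == "T") | (r == "T" & a == "C")
}

# Derive a per-component substream seed from one global seed, so that
# regenerating one component does not perturb the draws of another.
# Offsets are fixed per component name; results stay below 2^31.
component_seed <- function(seed, component) {
  offsets <- c(
    focal_vcf = 101L, panel = 211L, ppi = 307L, expression = 401L,
    genes = 503L, coverage = 601L, truth = 701L, features = 809L,
    annotations = 853L, pipeline = 907L
  )
  off <- offsets[[component]]
  if (is.null(off)) stop("unknown component: ", component)
  (as.integer(seed) + off) %% .Machine$integer.max
}

# Evaluate expr under a temporary RNG state seeded for one component.
with_component_seed <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(component_seed(seed, component))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# stopifnot with a friendlier message
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
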