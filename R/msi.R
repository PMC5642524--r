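#' Mononucleotide MSI markers
#' @return the five marker names
#' @export
msi_markers <- function() c("BAT-25", "BAT-26", "NR-21", "NR-24", "NR-27")

#' Marker allele-length profile
#'
#' @param marker_name one of [msi_markers()]
#' @param lengths integer allele lengths (bp)
#' @param fractions support fractions, must sum to 1
#' @return object of class `marker_profile`
#' @export
marker_profile <- function(marker_name, lengths, fractions) {
  if (!marker_name %in% msi_markers())
    abort("unknown MSI marker: ", marker_name)
  if (length(lengths) != length(fractions))
    abort("lengths and fractions differ in length")
  if (any(lengths <= 0) || any(lengths != round(lengths)))
    abort("allele lengths must be positive integers")
  if (abs(sum(fractions) - 1) > 1e-6)
    abort("support fractions must sum to 1")
  o <- order(lengths)
  structure(list(marker_name = marker_name,
                 lengths = as.integer(lengths[o]),
                 fractions = as.numeric(fractions[o])),
            class = "marker_profile")
}

#' Default parameters of the marker-instability rule
#'
#' The instability decision compares tumor and normal allele-length profiles:
#' a marker is unstable when tumor support at lengths absent from the normal
#' profile (beyond a +/- `tolerance_bp` window around any supported normal
#' allele) reaches `min_novel_fraction`, or when the modal allele length
#' shifts by more than `max_shift_bp`.
#'
#' @param min_novel_fraction minimum novel-allele mass to call instability
#' @param tolerance_bp window around normal alleles treated as concordant
#' @param max_shift_bp largest tolerated modal-length shift
#' @param support_floor normal-profile fractions at or below this are noise,
#'   not supported alleles
#' @return list of parameters
#' @export
msi_params <- function(min_novel_fraction = 0.2, tolerance_bp = 1L,
                       max_shift_bp = 1L, support_floor = 0.01) {
  list(min_novel_fraction = min_novel_fraction,
       tolerance_bp = as.integer(tolerance_bp),
       max_shift_bp = as.integer(max_shift_bp),
       support_floor = support_floor)
}

#' Assess one marker for instability
#'
#' @param tumor,normal [marker_profile()] objects for the same marker
#' @param params [msi_params()]
#' @return logical: TRUE when the marker is unstable in the tumor
#' @export
assess_marker <- function(tumor, normal, params = msi_params()) {
  if (tumor$marker_name != normal$marker_name)
    abort(sprintf("marker mismatch: tumor %s vs normal %s",
                  tumor$marker_name, normal$marker_name))
  norm_sup <- normal$lengths[normal$fractions > params$support_floor]
  novel <- vapply(tumor$lengths, function(l)
    all(abs(l - norm_sup) > params$tolerance_bp), logical(1))
  novel_mass <- sum(tumor$fractions[novel])
  mode_t <- tumor$lengths[which.max(tumor$fractions)]
  mode_n <- normal$lengths[which.max(normal$fractions)]
  novel_mass >= params$min_novel_fraction ||
    abs(mode_t - mode_n) > params$max_shift_bp
}

#' Combine five marker flags into an MSI status
#'
#' Zero unstable markers is microsatellite stable (MSS), exactly one is
#' low-frequency MSI (MSI-L), two or more is high-frequency MSI (MSI-H).
#'
#' @param per_marker_flags named (or ordered) logical vector of length 5
#' @return list of class `msi_result`: `per_marker_unstable`, `n_unstable`,
#'   `status`
#' @export
call_msi_status <- function(per_marker_flags) {
  if (length(per_marker_flags) != 5 || anyNA(per_marker_flags))
    abort("exactly five resolved marker flags are required")
  flags <- as.logical(per_marker_flags)
  if (is.null(names(flags))) names(flags) <- msi_markers()
  n <- sum(flags)
  status <- if (n == 0) "MSS" else if (n == 1) "MSI-L" else "MSI-H"
  structure(list(per_marker_unstable = flags, n_unstable = n,
                 status = status),
            class = "msi_result")
}

#' Call MSI status for a case from tumor/normal marker profiles
#'
#' @param tumor_profiles,normal_profiles named lists of [marker_profile()]s
#'   covering all five markers
#' @param params [msi_params()]
#' @return an `msi_result` (see [call_msi_status()])
#' @export
call_msi_case <- function(tumor_profiles, normal_profiles,
                          params = msi_params()) {
  flags <- vapply(msi_markers(), function(m) {
    if (is.null(tumor_profiles[[m]]) || is.null(normal_profiles[[m]]))
      abort("missing profile for marker ", m)
    assess_marker(tumor_profiles[[m]], normal_profiles[[m]], params)
  }, logical(1))
  call_msi_status(flags)
}

#' @export
print.msi_result <- function(x, ...) {
  cat("MSI status:", x$status, sprintf("(%d/5 markers unstable)\n",
                                       x$n_unstable))
  invisible(x)
}
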