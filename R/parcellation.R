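#' Giant-component profile of a network family
#'
#' Given networks built at increasing parcellation sizes n, records the
#' giant-component size n_G of each.  The profile is the input to the
#' resolution-selection rule: full brain coverage corresponds to n_G = n.
#'
#' @param networks List of [binary_network()] objects.
#' @param n Integer vector of parcellation sizes, one per network.  Defaults
#'   to each network's node count.
#' @return An object of class `resolution_profile`: data frame with columns
#'   `n`, `n_G`, sorted by `n`.
#' @export
resolution_profile <- function(networks, n = NULL) {
  if (length(networks) < 1) stop("at least one network is required")
  if (is.null(n)) n <- vapply(networks, function(x) x$n, numeric(1))
  n <- as.integer(n)
  if (length(n) != length(networks)) stop("n must have one entry per network")
  if (anyDuplicated(n)) stop("parcellation sizes must be distinct")
  ng <- vapply(networks, function(x) giant_component(x)$size, integer(1))
  out <- data.frame(n = n, n_G = ng)[order(n), ]
  rownames(out) <- NULL
  class(out) <- c("resolution_profile", "data.frame")
  out
}

#' Select the network resolution by the giant-component rule
#'
#' Returns the largest parcellation size n whose network is fully connected
#' (n_G = n): the finest resolution that still covers the whole brain with
#' one component.  Order of profile entries does not matter.
#'
#' @param profile A [resolution_profile()] (or data frame with columns `n`,
#'   `n_G`).
#' @return The selected n (integer).
#' @export
select_resolution <- function(profile) {
  if (!is.data.frame(profile) || !all(c("n", "n_G") %in% names(profile)))
    stop("profile must have columns n and n_G")
  if (nrow(profile) == 0) stop("profile is empty")
  ok <- profile$n[profile$n_G == profile$n]
  if (length(ok) == 0)
    stop("no parcellation satisfies n_G = n: even the coarsest network is disconnected")
  max(ok)
}

#' Cohort-level resolution selection
#'
#' Applies the giant-component rule jointly: the chosen resolution is the
#' largest n, within the grid shared by all subjects, at which every
#' subject's network is fully connected.  Use this to fix a single n for a
#' whole cohort; [select_resolution()] gives the per-subject choice.
#'
#' @param profiles List of [resolution_profile()] objects (one per subject).
#' @return List with `cohort_n` (the joint choice) and `per_subject`
#'   (named integer vector of individual selections, `NA` where no n
#'   qualifies).
#' @export
select_resolution_cohort <- function(profiles) {
  if (length(profiles) < 1) stop("at least one profile is required")
  grid <- Reduce(intersect, lapply(profiles, function(p) p$n))
  if (length(grid) == 0) stop("profiles share no common parcellation size")
  ok <- vapply(grid, function(nn) {
    all(vapply(profiles, function(p) p$n_G[p$n == nn] == nn, logical(1)))
  }, logical(1))
  if (!any(ok))
    stop("no common parcellation satisfies n_G = n for every subject")
  per <- vapply(profiles, function(p) {
    tryCatch(as.integer(select_resolution(p)), error = function(e) NA_integer_)
  }, integer(1))
  if (is.null(names(per)) && !is.null(names(profiles))) names(per) <- names(profiles)
  list(cohort_n = max(grid[ok]), per_subject = per)
}
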