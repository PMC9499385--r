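#' Default cell-of-origin miRNA panels
#'
#' Ships the package's default attribution panels for circulating plasma
#' miRNAs: the top-10 putative RBC-derived species, the top-10 putative
#' platelet-derived species, and additional hemolysis-susceptible miRNAs
#' that are not abundant in RBCs. miR-191-5p is abundant in both RBCs and
#' platelets and therefore appears in both top-10 lists; conflict resolution
#' (see \code{\link{resolve_panels}}) assigns it to the RBC panel. Panels are
#' study inputs, not algorithm outputs, and can be overridden by the user.
#'
#' @return A list with character vectors \code{rbc}, \code{platelet},
#'   \code{hemolysis_susceptible}.
#' @export
default_origin_panels <- function() {
  list(
    rbc = c("miR-451a", "miR-486-5p", "miR-92a-3p", "miR-16-5p",
            "miR-191-5p", "miR-25-3p", "miR-484", "miR-93-5p",
            "miR-181a-5p", "miR-486-3p"),
    platelet = c("miR-223-3p", "miR-126-3p", "miR-21-5p", "miR-150-5p",
                 "miR-23a-3p", "miR-103a-3p", "miR-320a", "miR-27b-3p",
                 "miR-199a-3p", "miR-191-5p"),
    hemolysis_susceptible = c("miR-144-3p", "miR-144-5p", "miR-4732-3p",
                              "miR-425-5p", "miR-15b-5p", "miR-16-2-3p")
  )
}

#' Resolve origin panels against an analysis universe
#'
#' Deterministically resolves membership conflicts and completes the
#' partition: miRNAs listed in both the RBC and the platelet panel are
#' assigned to the RBC panel (and the move is logged); the
#' hemolysis-susceptible panel excludes anything already RBC-assigned;
#' every other analyzed miRNA falls into \code{other}.
#'
#' @param panels a list as returned by \code{\link{default_origin_panels}}.
#' @param universe character vector of all analyzed miRNA names.
#' @return A list with \code{rbc}, \code{platelet},
#'   \code{hemolysis_susceptible}, \code{other} (disjoint, union =
#'   \code{universe}) and a \code{conflict_log} data.frame.
#' @export
resolve_panels <- function(panels, universe) {
  stopifnot(is.list(panels), all(c("rbc", "platelet") %in% names(panels)))
  hs <- panels$hemolysis_susceptible
  if (is.null(hs)) hs <- character(0)
  shared <- intersect(panels$rbc, panels$platelet)
  platelet <- setdiff(panels$platelet, shared)
  rbc <- unique(panels$rbc)
  hs <- setdiff(hs, c(rbc, platelet))
  rbc <- intersect(rbc, universe)
  platelet <- intersect(platelet, universe)
  hs <- intersect(hs, universe)
  if (length(intersect(rbc, platelet)) > 0)
    stop("origin panels overlap after conflict resolution")
  other <- setdiff(universe, c(rbc, platelet, hs))
  log <- data.frame(mirna = shared,
                    resolution = rep("assigned_to_rbc", length(shared)),
                    stringsAsFactors = FALSE)
  list(rbc = rbc, platelet = platelet, hemolysis_susceptible = hs,
       other = other, conflict_log = log)
}
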