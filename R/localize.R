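## Restriction-region localization from deletion-derivative panels.

.asRetained <- function(x) {
  if (is(x, "IRanges")) return(IRanges::reduce(x))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("retained intervals need two columns (start, end)")
  IRanges::reduce(IRanges(start = as.integer(x[, 1L]),
                          end = as.integer(x[, 2L])))
}

#' Create a Construct
#'
#' @param id construct label.
#' @param retained retained intervals on the parent coordinate system:
#'   an \link[IRanges]{IRanges} or a 2-column matrix/data.frame of 1-based
#'   inclusive \code{start, end} pairs; overlapping intervals are merged.
#' @param efficiency transformation efficiency (transformants per
#'   microgram); 0 encodes "not detected", NA missing.
#' @param role \code{"test"} or \code{"control"}.
#' @param control id of the construct's stated control (NA: use the panel
#'   default control).
#' @return a \linkS4class{Construct}.
#' @export
construct <- function(id, retained, efficiency, role = "test",
                      control = NA_character_) {
  new("Construct", id = as.character(id), retained = .asRetained(retained),
      efficiency = as.numeric(efficiency), role = role,
      control = as.character(control))
}

#' Assemble a TransformabilityPanel
#'
#' @param parentLength parent coordinate system length (bp).
#' @param constructs list of \linkS4class{Construct}; at least one with
#'   role \code{"control"}.
#' @return a \linkS4class{TransformabilityPanel}.
#' @export
transformabilityPanel <- function(parentLength, constructs) {
  new("TransformabilityPanel", parentLength = as.integer(parentLength),
      constructs = constructs)
}

setMethod("show", "Construct", function(object) {
  iv <- if (length(object@retained))
    paste(sprintf("[%d,%d]", IRanges::start(object@retained),
                  IRanges::end(object@retained)), collapse = " ")
  else "(none)"
  cat(sprintf("Construct '%s' (%s): retains %s; efficiency %s\n",
              object@id, object@role, iv,
              format(object@efficiency, digits = 3)))
})

setMethod("show", "TransformabilityPanel", function(object) {
  cat(sprintf("TransformabilityPanel: %d construct(s) on a %d bp parent\n",
              length(object@constructs), object@parentLength))
  for (x in object@constructs) show(x)
})

#' Fold change between two efficiencies
#'
#' @param effA,effB efficiencies; \code{effA / effB} is returned.
#' @param rounded round to the nearest integer fold for reporting.
#' @return numeric ratio; \code{Inf} (with a warning) when \code{effB} is 0.
#' @examples
#' foldChange(1.6e3, 3.7e0, rounded = TRUE)  # 432
#' @export
foldChange <- function(effA, effB, rounded = FALSE) {
  if (effB == 0) {
    warning("division by zero: fold change reported as Inf")
    return(Inf)
  }
  fc <- effA / effB
  if (rounded) round(fc) else fc
}

#' Plasmid-curing efficiency from colony counts
#'
#' Percentage of antibiotic-sensitive (plasmid-cured) colonies among those
#' screened, rounded to the nearest percent.
#'
#' @param nSensitive number of sensitive (cured) colonies.
#' @param nTotal number screened.
#' @return percentage (0--100), nearest percent.
#' @examples
#' curingEfficiency(18, 36)  # 50
#' curingEfficiency(33, 36)  # 92
#' @export
curingEfficiency <- function(nSensitive, nTotal) {
  if (nTotal <= 0) stop("'nTotal' must be positive")
  if (nSensitive < 0 || nSensitive > nTotal)
    stop("'nSensitive' must lie in [0, nTotal]")
  round(100 * nSensitive / nTotal)
}

#' Call a construct's restriction phenotype from its efficiency
#'
#' A construct is \emph{restricted} when its transformation efficiency is
#' reduced at least \code{hi}-fold relative to its control, \emph{permissive}
#' when reduced at most \code{lo}-fold (including any improvement), and
#' \emph{indeterminate} in between.  An efficiency of 0 ("no transformants
#' detected") is restricted with infinite fold-reduction.
#'
#' @param efficiency construct efficiency (transformants per microgram).
#' @param controlEfficiency its control's efficiency (> 0).
#' @param hi fold-reduction at or above which the call is restricted
#'   (default 1e2).
#' @param lo fold-reduction at or below which the call is permissive
#'   (default 1e1).
#' @return list with \code{call} (\code{"restricted"}, \code{"permissive"}
#'   or \code{"indeterminate"}) and \code{foldReduction}.
#' @examples
#' callPhenotype(3.7e0, 3.7e4)  # restricted, 1e4-fold
#' callPhenotype(3.5e4, 3.7e4)  # permissive
#' @export
callPhenotype <- function(efficiency, controlEfficiency, hi = 1e2, lo = 1e1) {
  if (is.na(controlEfficiency) || controlEfficiency <= 0)
    stop("control efficiency must be > 0")
  if (lo >= hi) stop("'lo' must be below 'hi'")
  if (is.na(efficiency))
    return(list(call = "indeterminate", foldReduction = NA_real_))
  if (efficiency == 0)
    return(list(call = "restricted", foldReduction = Inf))
  fr <- controlEfficiency / efficiency
  call <- if (fr >= hi) "restricted" else if (fr <= lo) "permissive"
          else "indeterminate"
  list(call = call, foldReduction = fr)
}

## Phenotype table for a panel: one row per construct.
.panelPhenotypes <- function(panel, hi, lo) {
  ids <- vapply(panel@constructs, function(x) x@id, character(1))
  eff <- vapply(panel@constructs, function(x) x@efficiency, numeric(1))
  roles <- vapply(panel@constructs, function(x) x@role, character(1))
  ctrl <- vapply(panel@constructs, function(x) x@control, character(1))
  defaultCtrl <- ids[roles == "control"][1L]
  ctrl[is.na(ctrl)] <- defaultCtrl
  calls <- character(length(ids))
  fr <- numeric(length(ids))
  for (i in seq_along(ids)) {
    ce <- eff[match(ctrl[i], ids)]
    ph <- callPhenotype(eff[i], ce, hi = hi, lo = lo)
    calls[i] <- ph$call
    fr[i] <- ph$foldReduction
  }
  data.frame(id = ids, role = roles, efficiency = eff, control = ctrl,
             foldReduction = fr, call = calls, row.names = NULL)
}

#' Localize the restriction-sensitive region from a construct panel
#'
#' Infers the minimal region of the parent vector responsible for
#' restriction under a single-contiguous-region model: the candidate region
#' is the intersection of the retained intervals of all restricted
#' constructs, minus the union of the retained intervals of all permissive
#' constructs.  Controls are treated as permissive by definition.
#' Indeterminate constructs are excluded with a warning.  The result is
#' inconsistent when the candidate region is empty (e.g. a permissive
#' construct retains everything some restricted construct retains), with
#' per-construct witnesses.
#'
#' @param panel a \linkS4class{TransformabilityPanel}.
#' @param hi,lo phenotype thresholds, see \code{\link{callPhenotype}}.
#' @return a \linkS4class{LocalizationResult}.
#' @export
localizeRegion <- function(panel, hi = 1e2, lo = 1e1) {
  stopifnot(is(panel, "TransformabilityPanel"))
  ph <- .panelPhenotypes(panel, hi = hi, lo = lo)
  ind <- ph$id[ph$call == "indeterminate"]
  if (length(ind))
    warning("excluding indeterminate construct(s): ",
            paste(ind, collapse = ", "))
  restr <- which(ph$call == "restricted")
  perm <- which(ph$call == "permissive" | ph$role == "control")
  if (!length(restr))
    stop("nothing to localize: no restricted construct in the panel")
  if (!length(perm))
    stop("nothing to delimit against: no permissive construct in the panel")
  ret <- lapply(panel@constructs, function(x) x@retained)
  inter <- Reduce(IRanges::intersect, ret[restr])
  permUnion <- IRanges::reduce(do.call(c, ret[perm]))
  candidate <- IRanges::setdiff(inter, permUnion)
  witnesses <- character()
  consistent <- TRUE
  if (sum(IRanges::width(candidate)) == 0L) {
    consistent <- FALSE
    if (sum(IRanges::width(inter)) == 0L) {
      witnesses <- c(witnesses,
        "restricted constructs retain no common region")
    } else {
      ## name permissive constructs that cover the restricted intersection
      for (i in perm) {
        cov <- IRanges::setdiff(inter, ret[[i]])
        if (sum(IRanges::width(cov)) == 0L)
          witnesses <- c(witnesses, sprintf(
            "permissive construct '%s' fully retains the region common to all restricted constructs (%s)",
            ph$id[i],
            paste(ph$id[restr], collapse = ", ")))
      }
      if (!length(witnesses))
        witnesses <- "permissive retention jointly covers the restricted intersection"
    }
  } else {
    ## sanity: no permissive construct may fully retain the candidate
    for (i in perm) {
      if (sum(IRanges::width(IRanges::setdiff(candidate, ret[[i]]))) == 0L) {
        consistent <- FALSE
        witnesses <- c(witnesses, sprintf(
          "permissive construct '%s' fully retains the candidate region",
          ph$id[i]))
      }
    }
    for (i in restr)
      witnesses <- c(witnesses, sprintf(
        "restricted construct '%s' retains the candidate region", ph$id[i]))
  }
  new("LocalizationResult", candidate = candidate, consistent = consistent,
      phenotypes = ph, witnesses = witnesses)
}

setMethod("show", "LocalizationResult", function(object) {
  if (length(object@candidate))
    cat("Candidate region(s): ",
        paste(sprintf("[%d,%d]", IRanges::start(object@candidate),
                      IRanges::end(object@candidate)), collapse = " "),
        sprintf(" (%d bp)\n", sum(IRanges::width(object@candidate))))
  else cat("Candidate region: empty\n")
  cat("Consistent single-region explanation:",
      if (object@consistent) "yes" else "NO", "\n")
  print(object@phenotypes)
})

#' Printed transformability data for the shuttle-vector construct series
#'
#' The electrotransformation efficiencies (transformants per microgram of
#' plasmid DNA) printed for the 21 shuttle vectors and deletion/recoding
#' derivatives assayed on \emph{C. pasteurianum}, together with each
#' construct's stated comparator: deletion derivatives are compared to the
#' relevant unmodified control vector (pIMP1 or pMTL85141), while the
#' recoded vectors are compared to their unmodified restricted parents.
#' \code{efficiency} 0 encodes "no transformants detected".
#'
#' @return data.frame with columns \code{id}, \code{efficiency},
#'   \code{control}, \code{figure}.
#' @export
transformabilityData <- function() {
  path <- system.file("extdata", "transformability_panel.tsv",
                      package = "RMscout", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
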