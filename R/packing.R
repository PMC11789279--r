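#' Idealised radial-glia packing parameters
#'
#' Mean widths of the three measured parts of a radial glial cell (RGC),
#' used to scale the idealised packing model: the apical endfoot
#' (5.2 um), the radial process (1.6 um) and the cell body (7.7 um).
#' The model assumes endfoot packing sets the cell spacing and that RGCs
#' are straight (no curvature or intercalation).
#'
#' @param endfootWUm apical endfoot width in um (default 5.2).
#' @param processWUm radial process width in um (default 1.6).
#' @param bodyWUm cell body width in um (default 7.7).
#' @return validated parameter list of class `PackingParams`.
#' @export
packingParams <- function(endfootWUm = 5.2, processWUm = 1.6,
                          bodyWUm = 7.7) {
    stopIfNot(endfootWUm > 0 && processWUm > 0 && bodyWUm > 0,
              "all widths must be positive")
    stopIfNot(bodyWUm >= processWUm,
              "cell body cannot be narrower than the process")
    structure(list(endfootWUm = endfootWUm, processWUm = processWUm,
                   bodyWUm = bodyWUm),
              class = "PackingParams")
}

#' Required protrusion reach for a distal contact
#'
#' In the idealised arrangement a protrusion must span one intervening
#' structure to touch a non-neighbouring (distal) cell: emanating from an
#' apical endfoot it must cross one endfoot width; emanating from a
#' radial process it must cross one cell body width.
#'
#' @param origin `"endfoot"` or `"process"`.
#' @param params a [packingParams()] list.
#' @return required reach in um.
#' @examples
#' requiredReach("endfoot")   # 5.2
#' requiredReach("process")   # 7.7
#' @export
requiredReach <- function(origin = c("endfoot", "process"),
                          params = packingParams()) {
    origin <- match.arg(origin)
    stopifnot(inherits(params, "PackingParams"))
    switch(origin, endfoot = params$endfootWUm, process = params$bodyWUm)
}

#' Fraction of protrusions exceeding a reach threshold
#'
#' Strictly-greater counting ("longer than" the intervening width), so
#' the fraction is `#(length > threshold) / n`.
#'
#' @param lengthsUm protrusion lengths in um (non-empty).
#' @param thresholdUm reach threshold in um.
#' @return fraction in `[0, 1]`.
#' @examples
#' reachFraction(c(4, 6, 8), 5.2)   # 2/3
#' @export
reachFraction <- function(lengthsUm, thresholdUm) {
    stopIfNot(length(lengthsUm) >= 1, "need at least one length")
    mean(lengthsUm > thresholdUm)
}

#' Neighbour count under idealised endfoot packing
#'
#' Number of apical endfeet touching the focal cell's endfoot when
#' equal-width endfeet tile the apical surface: hexagonal close packing
#' gives 6 (the "minimum of six neighbours" of the idealised model),
#' square packing 4, and the 1D cross-section drawing 2. The count
#' depends only on the packing type, not on the widths.
#'
#' @param packing `"hexagonal"`, `"square"` or `"linear"`.
#' @return neighbour count.
#' @examples
#' neighbourCount("hexagonal")   # 6
#' @export
neighbourCount <- function(packing = c("hexagonal", "square", "linear")) {
    packing <- match.arg(packing)
    switch(packing, hexagonal = 6L, square = 4L, linear = 2L)
}

#' Distal-contact report for a protrusion length population
#'
#' Combines [requiredReach()] and [reachFraction()] for both origin
#' sites into one table: per origin, the reach a protrusion needs to
#' contact a distal cell and the fraction of the population long enough
#' to do so.
#'
#' @param lengthsUm protrusion lengths in um (non-empty).
#' @param params a [packingParams()] list.
#' @return data.frame with columns `origin`, `required_reach_um`,
#'   `fraction`.
#' @examples
#' contactReport(genProtrusionLengths(protrusionPopParams(n = 500)))
#' @export
contactReport <- function(lengthsUm, params = packingParams()) {
    origins <- c("endfoot", "process")
    reach <- vapply(origins, requiredReach, numeric(1), params = params)
    data.frame(origin = origins, required_reach_um = unname(reach),
               fraction = vapply(unname(reach),
                                 function(t) reachFraction(lengthsUm, t),
                                 numeric(1)),
               row.names = NULL)
}
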