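#' Construct a DomainMap
#'
#' @param ranges data.frame `chain, domain, first, last` (inclusive, 1-based
#'   residue ranges; a domain may span several rows).
#' @param composites named list of selection specifications (see
#'   [resolveSelection()]), e.g. headpiece/tailpiece splits or pulling and
#'   constraint groups.
#' @return validated [DomainMap-class].
#' @export
domainMap <- function(ranges, composites = list()) {
  new("DomainMap", ranges = as.data.frame(ranges, stringsAsFactors = FALSE),
      composites = composites)
}

#' Domain names of a map
#' @param map a [DomainMap-class].
#' @return character vector of `chain:domain` labels.
#' @export
domainNames <- function(map) {
  unique(paste(map@ranges$chain, map@ranges$domain, sep = ":"))
}

.expandRanges <- function(residues) {
  ## residues may be an integer vector, or a list of c(first,last) pairs
  if (is.list(residues))
    unlist(lapply(residues, function(r) seq.int(r[1], r[2])))
  else as.integer(residues)
}

#' The shipped integrin-style domain map
#'
#' Residue ranges of the two-chain ectodomain architecture this package
#' emulates: chain A (alpha-subunit analog) carries the beta-propeller
#' (1-438), thigh (439-600), calf-1 (601-738) and calf-2 (739-956); chain B
#' (beta-subunit analog) carries PSI (1-57), hybrid (58-110 and 354-434),
#' betaA (111-353), EGF1-4 (435-472, 473-522, 523-559, 560-599), the ankle
#' (600-605) and betaTD (606-690). Composites: `headpiece` (A 1-600 plus
#' B 1-472), `tailpiece` (the complement), the Calpha pulling groups
#' `pull_betaA` (B 113-117, 151-156, 190-197, 244-250, 306-310, 329-332)
#' and `pull_propeller` (A 22-26, 97-101, 160-164, 225-229, 279-283,
#' 343-347, 407-411), and the constraint group `constraint_betaTD`
#' (B 610-620, 639-642, 656-658, 665-670, 679-682).
#'
#' @return a [DomainMap-class].
#' @export
defaultDomainMap <- function() {
  r <- function(chain, domain, first, last)
    data.frame(chain = chain, domain = domain, first = first, last = last,
               stringsAsFactors = FALSE)
  ranges <- rbind(
    r("A", "propeller", 1, 438), r("A", "thigh", 439, 600),
    r("A", "calf1", 601, 738), r("A", "calf2", 739, 956),
    r("B", "PSI", 1, 57),
    r("B", "hybrid", 58, 110), r("B", "hybrid", 354, 434),
    r("B", "betaA", 111, 353),
    r("B", "EGF1", 435, 472), r("B", "EGF2", 473, 522),
    r("B", "EGF3", 523, 559), r("B", "EGF4", 560, 599),
    r("B", "ankle", 600, 605), r("B", "betaTD", 606, 690))
  composites <- list(
    headpiece = list(union = list(
      list(chain = "A", residues = list(c(1, 600))),
      list(chain = "B", residues = list(c(1, 472))))),
    tailpiece = list(union = list(
      list(chain = "A", residues = list(c(601, 956))),
      list(chain = "B", residues = list(c(473, 690))))),
    pull_betaA = list(chain = "B", caOnly = TRUE,
                      residues = list(c(113, 117), c(151, 156),
                                      c(190, 197), c(244, 250),
                                      c(306, 310), c(329, 332))),
    pull_propeller = list(chain = "A", caOnly = TRUE,
                          residues = list(c(22, 26), c(97, 101),
                                          c(160, 164), c(225, 229),
                                          c(279, 283), c(343, 347),
                                          c(407, 411))),
    constraint_betaTD = list(chain = "B", caOnly = TRUE,
                             residues = list(c(610, 620), c(639, 642),
                                             c(656, 658), c(665, 670),
                                             c(679, 682))))
  domainMap(ranges, composites)
}

#' Resolve a selection specification to atom serials
#'
#' A specification is a list whose fields each restrict the selection:
#' `chain` (chain IDs), `domains` (domain names looked up in `map`),
#' `residues` (integer vector, or list of `c(first, last)` ranges),
#' `names` (atom names), `serials` (explicit serials), `caOnly`
#' (keep only CA atoms), or `composite` (name of a composite stored in
#' `map`), or `union` (list of specifications whose results are united).
#' Resolution is deterministic: the result is sorted and unique, so it does
#' not depend on predicate order. An empty specification, like a predicate
#' matching nothing, yields an empty vector without error.
#'
#' @param model an [AtomicModel-class].
#' @param map a [DomainMap-class] (needed for `domains`/`composite`).
#' @param spec selection specification list.
#' @return sorted integer vector of atom serials.
#' @export
resolveSelection <- function(model, map = NULL, spec = list()) {
  a <- model@atoms
  if (!is.null(spec$composite)) {
    if (is.null(map) || is.null(map@composites[[spec$composite]]))
      stop("resolveSelection: unknown composite '", spec$composite,
           "'; known: ",
           paste(names(if (is.null(map)) list() else map@composites),
                 collapse = ", "))
    return(resolveSelection(model, map, map@composites[[spec$composite]]))
  }
  if (!is.null(spec$union)) {
    out <- integer(0)
    for (s in spec$union)
      out <- union(out, resolveSelection(model, map, s))
    return(sort(out))
  }
  fields <- c("chain", "domains", "residues", "names", "serials", "caOnly")
  if (!any(fields %in% names(spec))) return(integer(0))
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$chain)) keep <- keep & a$chain %in% spec$chain
  if (!is.null(spec$domains)) {
    r <- map@ranges
    known <- unique(r$domain)
    bad <- setdiff(spec$domains, known)
    if (length(bad) > 0)
      stop("resolveSelection: unknown domain(s) ",
           paste(bad, collapse = ", "), "; known: ",
           paste(known, collapse = ", "))
    dkeep <- rep(FALSE, nrow(a))
    sub <- r[r$domain %in% spec$domains, , drop = FALSE]
    if (!is.null(spec$chain))
      sub <- sub[sub$chain %in% spec$chain, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      dkeep <- dkeep | (a$chain == sub$chain[i] &
                        a$resid >= sub$first[i] & a$resid <= sub$last[i])
    keep <- keep & dkeep
  }
  if (!is.null(spec$residues))
    keep <- keep & a$resid %in% .expandRanges(spec$residues)
  if (!is.null(spec$names)) keep <- keep & a$name %in% spec$names
  if (!is.null(spec$serials)) keep <- keep & a$serial %in% spec$serials
  if (isTRUE(spec$caOnly)) keep <- keep & a$name == "CA"
  sort(a$serial[keep])
}
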