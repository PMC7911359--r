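#' @import methods
#' @importFrom Biostrings AAStringSet readBStringSet width writeXStringSet
#' @importFrom stats rnorm runif setNames optim chisq.test qchisq
#' @importFrom utils read.delim write.table head modifyList
NULL

## ---------------------------------------------------------------------------
## Alphabet
## ---------------------------------------------------------------------------

#' Potts alphabet over amino acids and the alignment gap
#'
#' The state space of the sequence model: the 20 canonical amino acids plus
#' the gap symbol `-`, for q = 21 states in total.  The gap is kept as a
#' first-class state so that deletions contribute to couplings and fields
#' exactly like residues.  Non-canonical residue letters (B, Z, X, U, O, ...)
#' are encoded to the gap state, which keeps q fixed at 21.
#'
#' @slot symbols ordered character vector of the q state symbols.
#' @slot gapState integer index (1-based) of the gap symbol within `symbols`.
#' @export
setClass("PottsAlphabet",
  representation(symbols = "character", gapState = "integer"))

setValidity("PottsAlphabet", function(object) {
  if (anyDuplicated(object@symbols)) return("alphabet symbols must be unique")
  if (length(object@gapState) != 1L ||
      object@gapState < 1L || object@gapState > length(object@symbols))
    return("gapState must index one of the symbols")
  if (object@symbols[object@gapState] != "-")
    return("the gap state must carry the '-' symbol")
  TRUE
})

#' Default 21-state amino-acid alphabet
#'
#' Gap first, then the canonical amino acids in alphabetical one-letter order.
#'
#' @return a [PottsAlphabet-class] with q = 21 and the gap as state 1.
#' @examples
#' ab <- pottsAlphabet()
#' nStates(ab)     # 21
#' gapState(ab)    # 1
#' @export
pottsAlphabet <- function() {
  new("PottsAlphabet",
      symbols = c("-", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
      gapState = 1L)
}

#' @describeIn PottsAlphabet-class number of states q
#' @param object,x a `PottsAlphabet`
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname PottsAlphabet-class
#' @export
setMethod("nStates", "PottsAlphabet", function(x) length(x@symbols))

#' @rdname PottsAlphabet-class
#' @export
setGeneric("gapState", function(x) standardGeneric("gapState"))
#' @rdname PottsAlphabet-class
#' @export
setMethod("gapState", "PottsAlphabet", function(x) x@gapState)

#' @rdname PottsAlphabet-class
#' @export
setGeneric("alphabetSymbols", function(x) standardGeneric("alphabetSymbols"))
#' @rdname PottsAlphabet-class
#' @export
setMethod("alphabetSymbols", "PottsAlphabet", function(x) x@symbols)

setMethod("show", "PottsAlphabet", function(object) {
  cat("PottsAlphabet: q =", length(object@symbols),
      "states [", paste(object@symbols, collapse = ""), "], gap = state",
      object@gapState, "\n")
})

## ---------------------------------------------------------------------------
## Alignments
## ---------------------------------------------------------------------------

#' Gapped alignment of one signaling domain
#'
#' A fixed-width multiple sequence alignment of either the HisKA
#' (histidine-kinase dimerization/phosphotransfer) domain, the REC
#' (response-regulator receiver) domain, or of concatenated HK+RR pairs.
#' Rows are stored as an `AAStringSet`; sequence identifiers are the set
#' names and must be unique.
#'
#' @slot seqs `AAStringSet`, equal-width, uniquely named.
#' @slot domainTag one of `"HK"`, `"RR"`, `"PAIRED"`.
#' @slot metadata free-form list (removal reports, seeds, provenance).
#' @export
setClass("DomainAlignment",
  representation(seqs = "AAStringSet", domainTag = "character",
                 metadata = "list"),
  prototype(domainTag = "HK", metadata = list()))

setValidity("DomainAlignment", function(object) {
  if (!object@domainTag %in% c("HK", "RR", "PAIRED"))
    return("domainTag must be HK, RR or PAIRED")
  n <- length(object@seqs)
  if (n > 0L) {
    if (is.null(names(object@seqs)) || any(names(object@seqs) == ""))
      return("all sequences must be named")
    if (anyDuplicated(names(object@seqs)))
      return("sequence ids must be unique within an alignment")
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) > 1L)
      return(sprintf("ragged alignment: widths %s", paste(unique(w), collapse = ", ")))
  }
  TRUE
})

#' Construct a DomainAlignment from character rows
#'
#' @param rows character vector of equal-length aligned rows.
#' @param ids unique sequence identifiers (defaults to names of `rows`).
#' @param domainTag `"HK"`, `"RR"` or `"PAIRED"`.
#' @param metadata optional list.
#' @return a [DomainAlignment-class].
#' @export
DomainAlignment <- function(rows, ids = names(rows), domainTag = "HK",
                            metadata = list()) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  if (length(rows) > 0L) {
    w <- nchar(rows)
    if (length(unique(w)) > 1L) {
      bad <- ids[w != w[1L]][1L]
      stop("ragged alignment rows; first offending id: ", bad)
    }
  }
  ss <- Biostrings::AAStringSet(rows)
  names(ss) <- ids
  new("DomainAlignment", seqs = ss, domainTag = domainTag, metadata = metadata)
}

#' @rdname DomainAlignment-class
#' @param x,object a `DomainAlignment`
#' @export
setGeneric("alnIds", function(x) standardGeneric("alnIds"))
#' @rdname DomainAlignment-class
#' @export
setMethod("alnIds", "DomainAlignment", function(x) names(x@seqs))

#' @rdname DomainAlignment-class
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))
#' @rdname DomainAlignment-class
#' @export
setMethod("alnRows", "DomainAlignment",
          function(x) setNames(as.character(x@seqs), names(x@seqs)))

#' @rdname DomainAlignment-class
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))
#' @rdname DomainAlignment-class
#' @export
setMethod("alnWidth", "DomainAlignment", function(x) {
  if (length(x@seqs) == 0L) {
    w <- x@metadata$n_columns
    if (is.null(w)) 0L else as.integer(w)
  } else Biostrings::width(x@seqs)[1L]
})

#' @rdname DomainAlignment-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname DomainAlignment-class
#' @export
setMethod("nSequences", "DomainAlignment", function(x) length(x@seqs))

#' @rdname DomainAlignment-class
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))
#' @rdname DomainAlignment-class
#' @export
setMethod("domainTag", "DomainAlignment", function(x) x@domainTag)

setMethod("show", "DomainAlignment", function(object) {
  cat(sprintf("DomainAlignment [%s]: %d sequences x %d columns\n",
              object@domainTag, nSequences(object), alnWidth(object)))
})

#' Concatenated HK+RR alignment with pairing provenance
#'
#' A `DomainAlignment` of concatenated rows (HK block followed by RR block)
#' together with the block widths and the pairing table that produced it.
#' With the HisKA and REC domains the paired frame is 67 + 112 = 179 columns.
#'
#' @slot LHK width of the HK block.
#' @slot LRR width of the RR block.
#' @slot pairTable data.frame with columns `hk_id`, `rr_id`.
#' @slot provenance `"cognate"` or `"scrambled"`.
#' @export
setClass("PairedAlignment", contains = "DomainAlignment",
  representation(LHK = "integer", LRR = "integer",
                 pairTable = "data.frame", provenance = "character"),
  prototype(provenance = "cognate"))

setValidity("PairedAlignment", function(object) {
  if (object@domainTag != "PAIRED") return("domainTag must be PAIRED")
  if (!object@provenance %in% c("cognate", "scrambled"))
    return("provenance must be cognate or scrambled")
  if (nSequences(object) > 0L &&
      alnWidth(object) != object@LHK + object@LRR)
    return("n_columns must equal LHK + LRR")
  if (!all(c("hk_id", "rr_id") %in% colnames(object@pairTable)))
    return("pairTable needs hk_id and rr_id columns")
  TRUE
})

#' @rdname PairedAlignment-class
#' @param x a `PairedAlignment`
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @rdname PairedAlignment-class
#' @export
setMethod("pairTable", "PairedAlignment", function(x) x@pairTable)

setMethod("show", "PairedAlignment", function(object) {
  cat(sprintf("PairedAlignment [%s]: %d pairs, %d + %d = %d columns\n",
              object@provenance, nSequences(object), object@LHK, object@LRR,
              object@LHK + object@LRR))
})

#' Integer-encoded alignment
#'
#' Alignment rows mapped to integer states 1..q under a [PottsAlphabet-class].
#' Row names carry the sequence identifiers.
#'
#' @slot states integer matrix, M sequences x L columns, entries in 1..q.
#' @slot alphabet the encoding alphabet.
#' @export
setClass("EncodedAlignment",
  representation(states = "matrix", alphabet = "PottsAlphabet"))

setValidity("EncodedAlignment", function(object) {
  s <- object@states
  if (length(s) > 0L) {
    q <- nStates(object@alphabet)
    if (anyNA(s) || min(s) < 1L || max(s) > q)
      return("states must lie in 1..q")
  }
  TRUE
})

#' @rdname EncodedAlignment-class
#' @param x an `EncodedAlignment`
#' @export
setGeneric("encodedStates", function(x) standardGeneric("encodedStates"))
#' @rdname EncodedAlignment-class
#' @export
setMethod("encodedStates", "EncodedAlignment", function(x) x@states)

setMethod("show", "EncodedAlignment", function(object) {
  cat(sprintf("EncodedAlignment: %d x %d, q = %d\n",
              nrow(object@states), ncol(object@states),
              nStates(object@alphabet)))
})

## ---------------------------------------------------------------------------
## DCA containers
## ---------------------------------------------------------------------------

#' Reweighted, pseudocounted site frequencies
#'
#' Single-site and pair frequencies of an encoded alignment after
#' identity-based sequence reweighting and pseudocount regularisation.
#' `f2` is stored as an (L q) x (L q) matrix whose (i,j) block holds
#' f2(i,j)(a,b); diagonal blocks are diag(f1(i,)).
#'
#' @slot f1 L x q single-site frequencies.
#' @slot f2 (Lq) x (Lq) pair frequencies.
#' @slot Meff effective sequence count (sum of weights).
#' @slot lambda pseudocount weight.
#' @slot weights per-sequence weights.
#' @slot refState reference state used downstream for gauge reduction (gap).
#' @export
setClass("SiteFrequencies",
  representation(f1 = "matrix", f2 = "matrix", Meff = "numeric",
                 lambda = "numeric", weights = "numeric",
                 refState = "integer"))

setValidity("SiteFrequencies", function(object) {
  L <- nrow(object@f1); q <- ncol(object@f1)
  if (nrow(object@f2) != L * q || ncol(object@f2) != L * q)
    return("f2 must be (Lq) x (Lq)")
  if (max(abs(rowSums(object@f1) - 1)) > 1e-9)
    return("each f1 row must sum to 1")
  TRUE
})

setMethod("show", "SiteFrequencies", function(object) {
  cat(sprintf("SiteFrequencies: L = %d, q = %d, Meff = %.2f, lambda = %.2f\n",
              nrow(object@f1), ncol(object@f1), object@Meff, object@lambda))
})

#' Potts model over an aligned sequence frame
#'
#' Couplings e_ij(a,b) and local fields h_i(a) of the global sequence model
#' H(s) = -sum_{i<j} e_ij(s_i,s_j) - sum_i h_i(s_i).  Couplings are stored
#' as an (L q) x (L q) matrix of q x q blocks; diagonal blocks are zero and
#' the matrix satisfies e_ij(a,b) = e_ji(b,a).  Models reported by
#' [fitMFDCA()] are in the zero-sum gauge.
#'
#' @slot couplings (Lq) x (Lq) block matrix of couplings.
#' @slot fields L x q local fields.
#' @slot L,q frame length and state count.
#' @slot gaugeTag `"zero-sum"` or `"reference-state"`.
#' @slot provenance `"cognate"`, `"scrambled"` or `"synthetic"`.
#' @slot metadata list (lambda, identityThreshold, Meff, seed, ...).
#' @export
setClass("PottsModel",
  representation(couplings = "matrix", fields = "matrix",
                 L = "integer", q = "integer", gaugeTag = "character",
                 provenance = "character", metadata = "list"),
  prototype(gaugeTag = "reference-state", provenance = "synthetic",
            metadata = list()))

setValidity("PottsModel", function(object) {
  Lq <- object@L * object@q
  if (nrow(object@couplings) != Lq || ncol(object@couplings) != Lq)
    return("couplings must be (Lq) x (Lq)")
  if (nrow(object@fields) != object@L || ncol(object@fields) != object@q)
    return("fields must be L x q")
  TRUE
})

#' @rdname PottsModel-class
#' @param x,object a `PottsModel`
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))
#' @rdname PottsModel-class
#' @export
setMethod("couplings", "PottsModel", function(x) x@couplings)

#' @rdname PottsModel-class
#' @export
setGeneric("fields", function(x) standardGeneric("fields"))
#' @rdname PottsModel-class
#' @export
setMethod("fields", "PottsModel", function(x) x@fields)

#' Extract the q x q coupling block e_ij(.,.)
#' @param model a [PottsModel-class]
#' @param i,j column indices (1-based)
#' @return q x q matrix
#' @export
couplingBlock <- function(model, i, j) {
  q <- model@q
  model@couplings[((i - 1L) * q + 1L):(i * q), ((j - 1L) * q + 1L):(j * q)]
}

setMethod("show", "PottsModel", function(object) {
  cat(sprintf("PottsModel [%s]: L = %d, q = %d, gauge = %s\n",
              object@provenance, object@L, object@q, object@gaugeTag))
})

#' Direct-information matrix
#'
#' Pairwise direct information (DI) of a Potts model: the mutual information
#' of the two-site direct distribution built from each coupling block with
#' marginal-matched auxiliary fields.  Higher DI marks more strongly coupled
#' column pairs.
#'
#' @slot di symmetric L x L matrix, zero diagonal, non-negative.
#' @slot ranking data.frame (i, j, di) sorted by decreasing di, ties broken
#'   lexicographically on (i, j).
#' @slot convergence list: per-pair iteration counts and any non-converged
#'   pairs.
#' @export
setClass("DIMatrix",
  representation(di = "matrix", ranking = "data.frame",
                 convergence = "list"),
  prototype(convergence = list()))

setMethod("show", "DIMatrix", function(object) {
  cat(sprintf("DIMatrix: %d x %d, %d scored pairs, max DI = %.4g\n",
              nrow(object@di), ncol(object@di), nrow(object@ranking),
              if (nrow(object@ranking)) object@ranking$di[1L] else NA_real_))
})

## ---------------------------------------------------------------------------
## Structure / mask containers
## ---------------------------------------------------------------------------

#' One chain of a template complex structure
#'
#' Heavy-atom coordinates of a single chain, hydrogens dropped and alternate
#' locations resolved to the highest-occupancy conformer.
#'
#' @slot chainId PDB chain identifier.
#' @slot atoms data.frame with columns resno, resid, atom, x, y, z.
#' @export
setClass("StructureChain",
  representation(chainId = "character", atoms = "data.frame"))

setValidity("StructureChain", function(object) {
  need <- c("resno", "resid", "atom", "x", "y", "z")
  if (!all(need %in% colnames(object@atoms)))
    return("atoms needs columns resno, resid, atom, x, y, z")
  TRUE
})

setMethod("show", "StructureChain", function(object) {
  cat(sprintf("StructureChain %s: %d residues, %d heavy atoms\n",
              object@chainId, length(unique(object@atoms$resno)),
              nrow(object@atoms)))
})

#' Interfacial contact mask on the paired alignment frame
#'
#' The set of inter-domain column pairs lying within the structural distance
#' cutoff of the template HK-RR complex.  Every pair straddles the domain
#' boundary: `hk_col` in 1..LHK and `rr_col` in (LHK+1)..(LHK+LRR), both in
#' the concatenated frame.
#'
#' @slot pairs data.frame with columns hk_col, rr_col, min_dist.
#' @slot cutoffA distance cutoff in Angstrom (contacts are strictly closer).
#' @slot metricTag distance convention ("min-heavy-atom", "ca", "cb",
#'   or "planted" for synthetic masks).
#' @slot LHK,LRR block widths of the frame the mask applies to.
#' @export
setClass("ContactMask",
  representation(pairs = "data.frame", cutoffA = "numeric",
                 metricTag = "character", LHK = "integer", LRR = "integer"),
  prototype(metricTag = "min-heavy-atom"))

setValidity("ContactMask", function(object) {
  p <- object@pairs
  if (!all(c("hk_col", "rr_col") %in% colnames(p)))
    return("pairs needs hk_col and rr_col columns")
  if (nrow(p) > 0L) {
    if (any(p$hk_col < 1L | p$hk_col > object@LHK))
      return("hk_col must lie in the HK block")
    if (any(p$rr_col <= object@LHK | p$rr_col > object@LHK + object@LRR))
      return("rr_col must lie in the RR block of the concatenated frame")
    if (anyDuplicated(p[, c("hk_col", "rr_col")]))
      return("duplicate contact pairs")
  }
  TRUE
})

#' @rdname ContactMask-class
#' @param x a `ContactMask`
#' @export
setGeneric("maskPairs", function(x) standardGeneric("maskPairs"))
#' @rdname ContactMask-class
#' @export
setMethod("maskPairs", "ContactMask", function(x) x@pairs)

setMethod("show", "ContactMask", function(object) {
  cat(sprintf("ContactMask: %d inter-domain pairs, cutoff %.1f A (%s), frame %d + %d\n",
              nrow(object@pairs), object@cutoffA, object@metricTag,
              object@LHK, object@LRR))
})

## ---------------------------------------------------------------------------
## Scoring containers
## ---------------------------------------------------------------------------

#' Decomposed interface-masked Hamiltonian score
#'
#' The H_TCS score of one HK-RR sequence pair split into its masked
#' inter-domain coupling contribution and its local-field contribution:
#' `total = -couplingSum - fieldSum`.
#'
#' @slot couplingSum sum of e_ij over mask pairs at the pair's states.
#' @slot fieldSum sum of h_i over all concatenated positions.
#' @slot total the H_TCS value.
#' @export
setClass("ScoreComponents",
  representation(couplingSum = "numeric", fieldSum = "numeric",
                 total = "numeric"))

setValidity("ScoreComponents", function(object) {
  if (abs(object@total - (-object@couplingSum - object@fieldSum)) > 1e-9)
    return("total must equal -couplingSum - fieldSum")
  TRUE
})

setMethod("show", "ScoreComponents", function(object) {
  cat(sprintf("H_TCS = %.6f (coupling %.6f, field %.6f)\n",
              object@total, object@couplingSum, object@fieldSum))
})

#' Organism-wide specificity matrix
#'
#' H_TCS^specific values for every HK x RR combination of one organism (or
#' toy world).  More negative means stronger encoded interaction specificity;
#' values near zero mean shared two-component attributes only; positive
#' values mean loss of shared attributes.
#'
#' @slot scores numeric matrix, rownames = HK ids, colnames = RR ids.
#' @slot provenance list describing the cognate and null models used.
#' @export
setClass("SpecificityMatrix",
  representation(scores = "matrix", provenance = "list"),
  prototype(provenance = list()))

setValidity("SpecificityMatrix", function(object) {
  s <- object@scores
  if (length(s) > 0L) {
    if (is.null(rownames(s)) || is.null(colnames(s)))
      return("scores must carry HK row names and RR column names")
    if (any(!is.finite(s))) return("all scores must be finite")
  }
  TRUE
})

#' @rdname SpecificityMatrix-class
#' @param x a `SpecificityMatrix`
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname SpecificityMatrix-class
#' @export
setMethod("scores", "SpecificityMatrix", function(x) x@scores)

setMethod("show", "SpecificityMatrix", function(object) {
  cat(sprintf("SpecificityMatrix: %d HKs x %d RRs, range [%.3f, %.3f]\n",
              nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
})

#' Network rescoring after in-silico mutation
#'
#' @slot mutated the rescored [SpecificityMatrix-class].
#' @slot deltas per-cell score change (mutated - wild type).
#' @slot wt the wild-type matrix.
#' @export
setClass("MutationResult",
  representation(mutated = "SpecificityMatrix", deltas = "matrix",
                 wt = "SpecificityMatrix"))

setMethod("show", "MutationResult", function(object) {
  cat(sprintf("MutationResult: %d cells changed, max |delta| = %.4g\n",
              sum(object@deltas != 0), max(abs(object@deltas))))
})

## ---------------------------------------------------------------------------
## Synthetic world
## ---------------------------------------------------------------------------

#' Planted-coupling toy two-component world
#'
#' A synthetic organism for end-to-end validation: HK and RR family
#' alignments sampled from a Potts model whose inter-domain couplings live
#' only on a planted interface mask, a cognate pairing table (one RR family
#' per HK family), and the generating model itself.
#'
#' @slot hkAlignment,rrAlignment sampled [DomainAlignment-class]s.
#' @slot pairs cognate pairing data.frame (hk_id, rr_id).
#' @slot mask the planted [ContactMask-class].
#' @slot model the shared generating [PottsModel-class].
#' @slot familyBias L x nFamilies-style list of per-family HK field biases.
#' @slot families data.frame mapping sequence ids to family index.
#' @slot seed master seed.
#' @slot params generator parameters actually used.
#' @export
setClass("ToyWorld",
  representation(hkAlignment = "DomainAlignment",
                 rrAlignment = "DomainAlignment",
                 pairs = "data.frame", mask = "ContactMask",
                 model = "PottsModel", familyBias = "list",
                 families = "data.frame", seed = "integer",
                 params = "list"))

setMethod("show", "ToyWorld", function(object) {
  cat(sprintf(
    "ToyWorld: %d families, %d HK x %d RR sequences, %d planted interface pairs (seed %d)\n",
    object@params$nFamilies, nSequences(object@hkAlignment),
    nSequences(object@rrAlignment), nrow(maskPairs(object@mask)),
    object@seed))
})
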