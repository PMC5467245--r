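#' Initialize a lattice sacculus
#'
#' The sacculus is abstracted to an axial sequence of glycan strands per
#' layer (innermost first); circumferential strand extent is not modelled.
#' A layer of n strands spans n - 1 peptide-bridge units; the axial length
#' of the sacculus is tracked in bridge units. All initial strands are
#' stress-bearing and turnover starts at zero.
#'
#' @param n_strands Strands per layer (>= 2).
#' @param n_layers Number of layers (>= 1; 1 for Gram-negative
#'   monolayered, >= 2 for Gram-positive multilayered walls).
#' @return An object of class `sacculus`.
#' @export
init_sacculus <- function(n_strands, n_layers = 1) {
  if (!(n_strands >= 2)) stop("need at least 2 strands per layer")
  if (!(n_layers >= 1)) stop("need at least 1 layer")
  layers <- lapply(seq_len(n_layers), function(i)
    list(strand_ids = seq.int((i - 1) * n_strands + 1,
                              length.out = n_strands),
         state = "stress-bearing"))
  structure(list(layers = layers,            # innermost first
                 nascent = integer(0),       # strands of the layer in
                 # construction (3-under-2 only)
                 consumed = rep(FALSE, floor(n_strands / 2)),
                 next_id = n_strands * n_layers + 1L,
                 released = 0L,
                 created = 0L,
                 length_bridges = n_strands - 1L,
                 initial_strands = n_strands * n_layers),
            class = "sacculus")
}

#' Total strands currently in the sacculus (all layers plus nascent)
#' @param sac A `sacculus`.
#' @return Integer count.
#' @export
n_strands_total <- function(sac) {
  sum(vapply(sac$layers, function(l) length(l$strand_ids), integer(1))) +
    length(sac$nascent)
}

#' Apply one 3-for-1 insertion event (monolayered sacculus)
#'
#' One existing strand is replaced by three new strands hooked in at its
#' position: the old strand is released (turnover + 1), the strand count
#' grows by 2 and the sacculus expands by two peptide-bridge units.
#'
#' @param sac A monolayered `sacculus`.
#' @param position Index (1-based) of the strand to replace.
#' @return The updated `sacculus`.
#' @export
apply_3for1 <- function(sac, position) {
  stopifnot(inherits(sac, "sacculus"))
  if (length(sac$layers) != 1)
    stop("3-for-1 applies to a monolayered sacculus")
  ids <- sac$layers[[1]]$strand_ids
  if (position < 1 || position > length(ids))
    stop("position out of range")
  new_ids <- seq.int(sac$next_id, length.out = 3)
  sac$layers[[1]]$strand_ids <-
    append(ids[-position], new_ids, after = position - 1)
  sac$next_id <- sac$next_id + 3L
  sac$created <- sac$created + 3L
  sac$released <- sac$released + 1L
  sac$length_bridges <- sac$length_bridges + 2L
  sac
}

#' Apply one 3-under-2 insertion event (multilayered sacculus)
#'
#' Three new strands are added to the nascent innermost layer underneath
#' one template site - a disjoint pair of adjacent strands of the
#' stress-bearing layer. Each event expands the sacculus axially by one
#' peptide-bridge unit. No strand is released at event level; when every
#' template site of the stress-bearing layer has been consumed the layer
#' stack matures inside-to-outside: the completed nascent layer becomes
#' the new stress-bearing (template) layer, and the outermost old layer is
#' shed, releasing all its strands at once.
#'
#' @param sac A multilayered `sacculus`.
#' @param position Template-site index, 1 ... floor(n/2) where n is the
#'   current template-layer strand count; site k covers strands
#'   (2k - 1, 2k).
#' @return The updated `sacculus`.
#' @export
apply_3under2 <- function(sac, position) {
  stopifnot(inherits(sac, "sacculus"))
  if (length(sac$layers) < 2)
    stop("3-under-2 applies to a multilayered sacculus")
  if (position < 1 || position > length(sac$consumed))
    stop("template position out of range")
  if (sac$consumed[position])
    stop("template site ", position, " already consumed")
  new_ids <- seq.int(sac$next_id, length.out = 3)
  sac$nascent <- c(sac$nascent, new_ids)
  sac$next_id <- sac$next_id + 3L
  sac$created <- sac$created + 3L
  sac$consumed[position] <- TRUE
  sac$length_bridges <- sac$length_bridges + 1L
  if (all(sac$consumed)) sac <- .mature_layers(sac)
  sac
}

# inside-to-outside maturation: nascent layer completed -> becomes the new
# innermost stress-bearing layer; outermost layer shed (all strands
# released)
.mature_layers <- function(sac) {
  outer_ids <- sac$layers[[length(sac$layers)]]$strand_ids
  sac$released <- sac$released + length(outer_ids)
  sac$layers[[length(sac$layers)]] <- NULL
  for (i in seq_along(sac$layers)) sac$layers[[i]]$state <- "old"
  sac$layers <- c(list(list(strand_ids = sac$nascent,
                            state = "stress-bearing")), sac$layers)
  sac$consumed <- rep(FALSE, floor(length(sac$nascent) / 2))
  sac$nascent <- integer(0)
  sac
}

#' Run a growth trajectory under an insertion model
#'
#' Applies `n_events` insertion events sequentially, choosing positions by
#' the given policy, and records the state after every event.
#'
#' @param model `"3for1"` or `"3under2"`.
#' @param sac An [init_sacculus()] (monolayered for 3-for-1, multilayered
#'   for 3-under-2).
#' @param n_events Number of events to apply.
#' @param policy `"sequential"` (lowest available position) or `"random"`.
#' @param seed Integer seed (used by the random policy).
#' @return List with `trajectory` (data frame: `event`,
#'   `length_bridges`, `n_strands`, `released`) , the final `sacculus`
#'   and `truncated` (TRUE if positions were exhausted early).
#' @export
run_growth <- function(model = c("3for1", "3under2"), sac, n_events,
                       policy = c("sequential", "random"), seed = 1) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  set.seed(seed)
  rows <- vector("list", n_events)
  truncated <- FALSE
  for (e in seq_len(n_events)) {
    if (model == "3for1") {
      n <- length(sac$layers[[1]]$strand_ids)
      pos <- if (policy == "random") sample.int(n, 1) else 1L
      sac <- apply_3for1(sac, pos)
    } else {
      avail <- which(!sac$consumed)
      if (!length(avail)) { truncated <- TRUE; break }
      pos <- if (policy == "random") avail[sample.int(length(avail), 1)]
      else avail[1]
      sac <- apply_3under2(sac, pos)
    }
    rows[[e]] <- data.frame(event = e,
                            length_bridges = sac$length_bridges,
                            n_strands = n_strands_total(sac),
                            released = sac$released)
  }
  list(trajectory = do.call(rbind, rows), sacculus = sac,
       truncated = truncated)
}
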