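#' @include AllClasses.R AllGenerics.R
NULL

# Occupancy-based lattice neighbour lookup: n x 4 matrix of agent
# indices in N, S, W, E order; 0 marks "no agent".
.neighborIndex <- function(net) {
  n <- nAgents(net)
  if (n == 0) return(matrix(0L, 0, 4))
  nx <- net@grid_nx; ny <- net@grid_ny
  occ <- matrix(0L, nx, ny)
  s <- net@sites
  occ[s] <- seq_len(n)
  look <- function(dr, dc) {
    r <- s[, 1] + dr; cc <- s[, 2] + dc
    ok <- r >= 1 & r <= nx & cc >= 1 & cc <= ny
    out <- integer(n)
    out[ok] <- occ[cbind(r[ok], cc[ok])]
    out
  }
  cbind(look(-1L, 0L), look(1L, 0L), look(0L, -1L), look(0L, 1L))
}

# Segment-incidence degree per agent (0 for unconnected agents).
.agentDegree <- function(net) {
  tabulate(as.vector(net@segments), nbins = nAgents(net))
}

# Mean Dll4 over occupied lattice neighbours (0 if isolated).
.neighborDll4 <- function(net, nb = .neighborIndex(net)) {
  n <- nAgents(net)
  if (n == 0) return(numeric(0))
  d4 <- net@state[, "D4"]
  tot <- numeric(n); cnt <- numeric(n)
  for (k in 1:4) {
    idx <- nb[, k]
    has <- idx > 0L
    tot[has] <- tot[has] + d4[idx[has]]
    cnt <- cnt + as.numeric(has)
  }
  ifelse(cnt > 0, tot / cnt, 0)
}

#' Seed angiogenic sprouts on the domain boundary
#'
#' Places quiescent endothelial agents on the domain perimeter, one
#' every `sprout_seed_spacing` sites walking the perimeter clockwise
#' from the top-left corner (corners are visited once). Each seeded
#' agent roots its own sprout, so vessels can grow into the implant
#' from all four sides. The construction is deterministic.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return a [VascularNetwork-class] with boundary agents only.
#' @examples
#' nAgents(seedBoundarySprouts(scenarioConfig()))  # 40
#' @export
seedBoundarySprouts <- function(cfg, p = defaultParameters()) {
  nx <- cfg@grid_nx; ny <- cfg@grid_ny
  spacing <- as.integer(p@sprout_seed_spacing)
  if (spacing < 1L) stop("sprout_seed_spacing must be >= 1")
  if (spacing > min(nx, ny))
    stop("sprout_seed_spacing exceeds the domain edge length")
  per <- rbind(
    cbind(1L, seq_len(ny)),                       # top, left to right
    cbind(seq(2L, nx), ny),                       # right, downwards
    cbind(nx, seq(ny - 1L, 1L)),                  # bottom, right to left
    cbind(seq(nx - 1L, 2L), 1L))                  # left, upwards
  pick <- seq(1L, nrow(per), by = spacing)
  sites <- per[pick, , drop = FALSE]
  n <- nrow(sites)
  state <- matrix(0, n, 8, dimnames = list(NULL, .STATE_NAMES))
  new("VascularNetwork",
      sites = sites, role = rep("quiescent", n), state = state,
      sprout_id = seq_len(n), segments = matrix(0L, 0, 2),
      perfused = logical(0), boundary_roots = seq_len(n),
      grid_nx = nx, grid_ny = ny)
}

#' One explicit step of the intracellular Dll4-Notch dynamics
#'
#' Advances the 8-species endothelial state by one explicit Euler step
#' of the lateral-inhibition system. VEGF binding activates VEGFR-2
#' (`Va`); the effective active receptor is algebraically attenuated by
#' effective Notch activity, `Ve = Va / (1 + (Ne / K)^2)`; `Ve` drives
#' sigmoidal Dll4 production; a neighbour's mean Dll4 activates Notch1
#' (`Na`), whose effective level `Ne` tracks it; actin `A` relaxes
#' towards `Ve` and confers tip competence once above `theta_tip`.
#' Receptor and Notch production are VEGF-gated, so the all-zero state
#' at zero VEGF is a fixed point. All species decay first-order and
#' remain nonnegative.
#'
#' @param state numeric vector of length 8 or an `n x 8` matrix with
#'   columns `V, Va, Ve, N, Na, Ne, D4, A`.
#' @param vegf local VEGF concentration(s).
#' @param p a [ModelParameters-class].
#' @param dt time step (days), `>= 0`.
#' @param neighborDll4 mean Dll4 presented by lattice-neighbour agents
#'   (0 for an isolated cell).
#' @return the updated state, same shape as the input.
#' @export
notchStep <- function(state, vegf, p = defaultParameters(), dt,
                      neighborDll4 = 0) {
  if (dt < 0) stop("dt must be >= 0")
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, 1, 8, dimnames = list(NULL, .STATE_NAMES))
  if (ncol(state) != 8) stop("state must have 8 species")
  V <- state[, 1]; Va <- state[, 2]; N <- state[, 4]
  Na <- state[, 5]; Ne <- state[, 6]; D4 <- state[, 7]; A <- state[, 8]
  Ve <- Va / (1 + (Ne / p@K_notch_inh)^2)
  gate <- vegf / (vegf + p@K_vegf_gate)

  Vn  <- V + dt * (p@notch_alpha * gate - p@notch_delta * V - p@k_on * vegf * V)
  Van <- Va + dt * (p@k_on * vegf * V - p@notch_delta * Va)
  D4n <- D4 + dt * (p@dll4_max * Ve^2 / (Ve^2 + p@K_dll4^2) -
                      p@notch_delta * D4)
  Nn  <- N + dt * (p@notch_alpha * gate - p@notch_delta * N -
                     p@k_notch * N * neighborDll4)
  Nan <- Na + dt * (p@k_notch * N * neighborDll4 - p@notch_delta * Na)
  Nen <- Ne + dt * p@notch_delta * (Na - Ne)
  An  <- A + dt * p@notch_delta * (Ve - A)

  out <- cbind(V = pmax(Vn, 0), Va = pmax(Van, 0), Ve = 0,
               N = pmax(Nn, 0), Na = pmax(Nan, 0), Ne = pmax(Nen, 0),
               D4 = pmax(D4n, 0), A = pmax(An, 0))
  out[, 3] <- out[, 2] / (1 + (out[, 6] / p@K_notch_inh)^2)
  if (vec) out[1, ] else out
}

#' Step the Dll4-Notch state of every agent in a network
#'
#' Synchronous [notchStep()] over all agents, with each agent reading
#' the VEGF field at its site and the mean Dll4 of its lattice-adjacent
#' neighbours.
#'
#' @param net a [VascularNetwork-class].
#' @param vegf_field VEGF matrix on the lattice.
#' @param p a [ModelParameters-class].
#' @param dt time step (days).
#' @param nb optional precomputed neighbour index (internal use).
#' @return the updated network.
#' @export
notchStepNetwork <- function(net, vegf_field, p = defaultParameters(), dt,
                             nb = NULL) {
  if (nAgents(net) == 0) return(net)
  if (is.null(nb)) nb <- .neighborIndex(net)
  g_local <- vegf_field[net@sites]
  # enclosed stalk cells (two or more vessel connections) sense less
  # VEGF than the filopodia-bearing free ends of a sprout
  enclosed <- .agentDegree(net) >= 2L
  g_local[enclosed] <- p@stalk_sensing * g_local[enclosed]
  net@state <- notchStep(net@state, g_local, p, dt, .neighborDll4(net, nb))
  net
}

#' Select tip cells by lateral inhibition
#'
#' An agent becomes a tip when its actin is at least `theta_tip` and
#' strictly exceeds the actin of every lattice-neighbour agent (ties
#' broken in favour of the smaller agent id), so no two adjacent agents
#' can both be tips. Tip role is persistent: a current tip keeps
#' leading while its actin stays above threshold (and suppresses
#' adjacent challengers), and is demoted to stalk once actin drops
#' below `theta_tip`. At most one tip exists per sprout (new tips are
#' only recruited in sprouts without one; highest actin wins, id
#' tie-break), so sprouts extend without branching, matching the
#' sprouting - growth - anastomosis sequence.
#'
#' @param net a [VascularNetwork-class] stepped to the current time.
#' @param vegf_field VEGF matrix (kept for interface symmetry;
#'   selection itself reads only the actin state).
#' @param p a [ModelParameters-class].
#' @return the updated network.
#' @export
selectTips <- function(net, vegf_field = NULL, p = defaultParameters()) {
  n <- nAgents(net)
  if (n == 0) return(net)
  A <- net@state[, "A"]
  role <- net@role
  # tips below threshold lose tip competence
  role[role == "tip" & A < p@theta_tip] <- "stalk"

  # only free chain ends can lead: unconnected agents, or the single-
  # connection head of a sprout (roots that have already sprouted and
  # agents enclosed by two or more segments cannot)
  deg <- .agentDegree(net)
  ids <- seq_len(n)
  is_end <- deg == 0L | (deg == 1L & !(ids %in% net@boundary_roots))

  nb <- .neighborIndex(net)
  beats_all <- rep(TRUE, n)
  for (k in 1:4) {
    idx <- nb[, k]
    # lateral inhibition is adjudicated against other sprouts; the
    # intra-sprout tip/stalk hierarchy is set by the chain-end rule
    has <- idx > 0L
    has[has] <- net@sprout_id[idx[has]] != net@sprout_id[has]
    ok <- !has
    ok[has] <- A[has] > A[idx[has]] |
      (A[has] == A[idx[has]] & ids[has] < idx[has])
    beats_all <- beats_all & ok
  }
  cand <- which(A >= p@theta_tip & beats_all & is_end & role != "tip")
  # a persisting tip suppresses adjacent challengers
  if (length(cand)) {
    tip_adjacent <- rep(FALSE, n)
    for (k in 1:4) {
      idx <- nb[, k]
      has <- idx > 0L
      tip_adjacent[has] <- tip_adjacent[has] | role[idx[has]] == "tip"
    }
    cand <- cand[!tip_adjacent[cand]]
  }
  # recruit at most one tip per sprout, only where none persists
  if (length(cand)) {
    has_tip <- unique(net@sprout_id[role == "tip"])
    cand <- cand[!net@sprout_id[cand] %in% has_tip]
  }
  if (length(cand)) {
    ord <- cand[order(net@sprout_id[cand], -A[cand], cand)]
    keep <- ord[!duplicated(net@sprout_id[ord])]
    role[keep] <- "tip"
  }
  net@role <- role
  net
}

.sprout_root <- function(net, sprout) {
  if (sprout %in% net@boundary_roots) sprout else NA_integer_
}

#' Advance tips up the VEGF gradient and fuse sprouts
#'
#' One growth event: each tip (in agent-id order) advances to the
#' unoccupied lattice-neighbour site with maximal VEGF (ties resolved
#' in N, E, S, W order); a new tip agent occupies the target site and
#' the vacated site keeps a stalk agent, connected by a new segment. A
#' tip that ends up adjacent to an agent of a different sprout fuses
#' with it (anastomosis): a segment is added, the tip retires to stalk,
#' and if the two sprouts are rooted at distinct boundary sites every
#' segment on the shortest root-to-root path through the fused network
#' is flagged perfused. Tips with no free neighbour stall without
#' error. Agents are never deleted.
#'
#' @param net a [VascularNetwork-class] with tips selected.
#' @param vegf_field VEGF matrix on the lattice.
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return the updated network.
#' @export
growAndAnastomose <- function(net, vegf_field, cfg = scenarioConfig(),
                              p = defaultParameters()) {
  n0 <- nAgents(net)
  if (n0 == 0) return(net)
  nx <- net@grid_nx; ny <- net@grid_ny
  occ <- matrix(0L, nx, ny)
  occ[net@sites] <- seq_len(n0)

  sites <- net@sites; role <- net@role; state <- net@state
  sprout <- net@sprout_id; segs <- net@segments; perf <- net@perfused
  # neighbour offsets in deterministic N, E, S, W order
  off <- rbind(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))

  for (a in which(net@role == "tip")) {
    r <- sites[a, 1]; cc <- sites[a, 2]
    nbr <- cbind(r + off[, 1], cc + off[, 2])
    inb <- nbr[, 1] >= 1 & nbr[, 1] <= nx & nbr[, 2] >= 1 & nbr[, 2] <= ny
    free <- inb
    free[inb] <- occ[nbr[inb, , drop = FALSE]] == 0L
    if (!any(free)) next  # stalled tip
    vals <- rep(-Inf, 4)
    vals[free] <- vegf_field[nbr[free, , drop = FALSE]]
    tgt <- nbr[which.max(vals), ]

    new_id <- nrow(sites) + 1L
    sites <- rbind(sites, tgt)
    role <- c(role, "tip")
    state <- rbind(state, state[a, ])  # the tip cell carries its state forward
    sprout <- c(sprout, sprout[a])
    role[a] <- "stalk"
    # the vacated site holds a newborn daughter stalk: it inherits the
    # cytoplasmic state but no accumulated Dll4, so it does not
    # transiently inhibit the tip it trails
    state[a, "D4"] <- 0
    occ[tgt[1], tgt[2]] <- new_id
    segs <- rbind(segs, c(a, new_id))
    perf <- c(perf, FALSE)

    # anastomosis: first different-sprout agent adjacent to the new site
    nbr2 <- cbind(tgt[1] + off[, 1], tgt[2] + off[, 2])
    inb2 <- nbr2[, 1] >= 1 & nbr2[, 1] <= nx & nbr2[, 2] >= 1 & nbr2[, 2] <= ny
    partner <- NA_integer_
    for (k in which(inb2)) {
      cand <- occ[nbr2[k, 1], nbr2[k, 2]]
      if (cand > 0L && cand != a && sprout[cand] != sprout[new_id]) {
        partner <- cand
        break
      }
    }
    if (!is.na(partner)) {
      segs <- rbind(segs, c(new_id, partner))
      perf <- c(perf, FALSE)
      role[new_id] <- "stalk"  # tip retires on fusion
      rootA <- .sprout_root(net, sprout[new_id])
      rootB <- .sprout_root(net, sprout[partner])
      if (!is.na(rootA) && !is.na(rootB) && rootA != rootB) {
        gr <- igraph::make_graph(t(segs), n = nrow(sites), directed = FALSE)
        ep <- igraph::shortest_paths(gr, from = rootA, to = rootB,
                                     output = "epath")$epath[[1]]
        if (length(ep)) perf[as.integer(ep)] <- TRUE
      }
    }
  }

  new("VascularNetwork",
      sites = sites, role = role, state = state,
      sprout_id = as.integer(sprout), segments = segs, perfused = perf,
      boundary_roots = net@boundary_roots,
      grid_nx = nx, grid_ny = ny)
}
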