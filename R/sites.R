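# Lipid binding-site analysis: dual-cutoff contact events, survival-curve
# residence times, residue-graph site clustering, representative poses.
#
# A contact event for a (lipid, residue) pair starts at the first frame
# where the minimum interparticle distance drops below r_on and ends at the
# first subsequent frame where it exceeds r_off (hysteresis suppresses
# flicker at the cutoff boundary). Event times are half-open [start, end)
# in ns with end = time of the last contacted frame + frame spacing, so a
# k-frame contact has duration k*dt.

# Per-frame minimum distance between every lipid residue and every protein
# residue: list(dist = [n_lipid, n_res, n_frames] array, lipids, residues).
contact_distance_array <- function(traj, protein_sel, lipid_sel) {
  stopifnot(inherits(traj, "Trajectory"))
  ip <- select_atoms(traj$topology, protein_sel)
  il <- select_atoms(traj$topology, lipid_sel)
  if (!length(ip)) stop("empty protein selection")
  if (!length(il)) stop("empty lipid selection")
  a <- traj$topology$atoms
  res_key <- paste(a$chain[ip], a$resid[ip], sep = "\r")
  residues <- residue_nodes(traj$topology, ip)
  res_group <- match(res_key, paste(residues$chain, residues$resid, sep = "\r"))
  lip_ids <- sort(unique(a$resid[il]))
  lip_group <- match(a$resid[il], lip_ids)
  nf <- n_frames(traj)
  nr <- nrow(residues); nl <- length(lip_ids)
  one_per_group <- length(ip) == nr && length(il) == nl
  perm_col <- match(seq_len(nr), res_group)
  perm_row <- match(seq_len(nl), lip_group)
  dist <- array(Inf, dim = c(nl, nr, nf))
  grp_cols <- split(seq_along(ip), res_group)
  grp_rows <- split(seq_along(il), lip_group)
  for (f in seq_len(nf)) {
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    D <- pair_dist_matrix(matrix(traj$coords[il, , f], ncol = 3),
                          matrix(traj$coords[ip, , f], ncol = 3), box)
    if (one_per_group) {
      dist[, , f] <- D[perm_row, perm_col]
    } else {
      # min over residue atoms, then over lipid atoms
      Dr <- matrix(Inf, length(il), nr)
      for (r in seq_len(nr)) {
        sub <- D[, grp_cols[[r]], drop = FALSE]
        Dr[, r] <- do.call(pmin, c(as.data.frame(sub), list(Inf)))
      }
      for (l in seq_len(nl)) {
        sub <- Dr[grp_rows[[l]], , drop = FALSE]
        dist[l, , f] <- do.call(pmin, c(as.data.frame(t(sub)), list(Inf)))
      }
    }
  }
  list(dist = dist, lipids = lip_ids, residues = residues)
}

#' Detect lipid-residue contact events with dual-cutoff hysteresis
#'
#' @param traj A `Trajectory`.
#' @param protein_sel Selection for protein atoms (grouped by residue).
#' @param lipid_sel Selection for lipid atoms (grouped by lipid residue id).
#' @param r_on Contact-start cutoff, Angstrom (default 4.75).
#' @param r_off Contact-end cutoff, Angstrom (default 7.0, must be >= r_on).
#' @param gap Frames: consecutive events of the same pair separated by at
#'   most this many frames are merged (0 = off, the default; hysteresis
#'   already absorbs boundary flicker).
#' @return data.frame of events (lipid_id, chain, resid, start_frame,
#'   end_frame, start, end in ns) with attributes `times`, `dt`,
#'   `total_time`, `residues`, `lipids` used by downstream estimators.
#' @export
detect_contacts <- function(traj, protein_sel, lipid_sel,
                            r_on = 4.75, r_off = 7.0, gap = 0) {
  if (r_off < r_on) stop("r_off (", r_off, ") must be >= r_on (", r_on, ")")
  if (r_on <= 0) stop("r_on must be positive")
  ca <- contact_distance_array(traj, protein_sel, lipid_sel)
  times <- traj$times
  nf <- length(times)
  dt <- if (nf > 1) stats::median(diff(times)) else 1
  ev <- list()
  nl <- dim(ca$dist)[1]; nr <- dim(ca$dist)[2]
  for (l in seq_len(nl)) for (r in seq_len(nr)) {
    d <- ca$dist[l, r, ]
    bound <- FALSE; sf <- 0L; last <- 0L
    for (f in seq_len(nf)) {
      if (!bound) {
        if (d[f] < r_on) { bound <- TRUE; sf <- f; last <- f }
      } else {
        if (d[f] > r_off) {
          ev[[length(ev) + 1L]] <- c(l, r, sf, last)
          bound <- FALSE
        } else last <- f
      }
    }
    if (bound) ev[[length(ev) + 1L]] <- c(l, r, sf, last)
  }
  if (length(ev)) {
    m <- do.call(rbind, ev)
    events <- data.frame(
      lipid_id = ca$lipids[m[, 1]],
      chain = ca$residues$chain[m[, 2]],
      resid = ca$residues$resid[m[, 2]],
      start_frame = m[, 3], end_frame = m[, 4],
      stringsAsFactors = FALSE)
    if (gap > 0) events <- stitch_events(events, gap)
    events$start <- times[events$start_frame]
    events$end <- times[events$end_frame] + dt
    events <- events[order(events$chain, events$resid, events$lipid_id,
                           events$start_frame), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(lipid_id = integer(0), chain = character(0),
                         resid = integer(0), start_frame = integer(0),
                         end_frame = integer(0), start = numeric(0),
                         end = numeric(0), stringsAsFactors = FALSE)
  }
  attr(events, "times") <- times
  attr(events, "dt") <- dt
  attr(events, "total_time") <- if (nf > 0) times[nf] - times[1] + dt else 0
  attr(events, "residues") <- ca$residues
  attr(events, "lipids") <- ca$lipids
  events
}

#' Merge events of the same pair separated by short gaps
#'
#' @param events Event data.frame (lipid_id, chain, resid, start_frame,
#'   end_frame).
#' @param gap Maximum separating gap in frames to stitch across.
#' @return Stitched event data.frame.
#' @export
stitch_events <- function(events, gap = 1) {
  if (nrow(events) < 2L || gap <= 0) return(events)
  key <- paste(events$lipid_id, events$chain, events$resid, sep = "\r")
  out <- lapply(split(seq_len(nrow(events)), key), function(ii) {
    e <- events[ii[order(events$start_frame[ii])], , drop = FALSE]
    keep <- e[1, , drop = FALSE]
    for (j in seq_len(nrow(e))[-1]) {
      if (e$start_frame[j] - keep$end_frame[nrow(keep)] - 1L <= gap) {
        keep$end_frame[nrow(keep)] <- max(keep$end_frame[nrow(keep)],
                                          e$end_frame[j])
      } else keep <- rbind(keep, e[j, , drop = FALSE])
    }
    keep
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  for (at in c("times", "dt", "total_time", "residues", "lipids"))
    attr(res, at) <- attr(events, at)
  res
}

#' Survival curve of contact-event durations
#'
#' `survival[k]` is the fraction of events whose duration is at least
#' `lags[k]`; survival(0) = 1 and the curve is non-increasing.
#'
#' @param durations Event durations, ns.
#' @param lags Optional lag grid (default: 0 plus the sorted unique
#'   durations).
#' @return List with `lags`, `survival`, `n_events`.
#' @export
survival_curve <- function(durations, lags = NULL) {
  durations <- durations[durations > 0]
  if (!length(durations)) return(list(lags = 0, survival = numeric(0), n_events = 0L))
  if (is.null(lags)) lags <- sort(unique(c(0, durations)))
  surv <- vapply(lags, function(l) mean(durations >= l - 1e-12), numeric(1))
  list(lags = lags, survival = surv, n_events = length(durations))
}

#' Residence time from a survival-curve fit
#'
#' 1/koff from a least-squares fit of log survival vs lag, restricted to
#' the well-sampled part of the curve (survival >= 0.05). Falls back to the
#' mean duration with fewer than `min_events` events or a degenerate fit.
#'
#' @param durations Contact-event durations, ns.
#' @param min_events Minimum events for the fit path (default 5).
#' @return Residence time in ns (0 for no events).
#' @export
fit_residence_time <- function(durations, min_events = 5) {
  durations <- durations[durations > 0]
  if (!length(durations)) return(0)
  if (length(durations) < min_events || length(unique(durations)) < 2L)
    return(mean(durations))
  sc <- survival_curve(durations)
  keep <- sc$survival >= 0.05 & sc$survival > 0
  if (sum(keep) < 2L) return(mean(durations))
  fit <- lm(log(sc$survival[keep]) ~ sc$lags[keep])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(mean(durations))
  as.numeric(-1 / slope)
}

# Total length of the union of half-open intervals [start, end).
interval_union_length <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i] }
  }
  tot + (ce - cs)
}

#' Per-residue residence times and occupancies from contact events
#'
#' @param events Event data.frame from [detect_contacts()].
#' @param total_time Total analyzed time in ns (default: the events'
#'   `total_time` attribute).
#' @return data.frame per residue: chain, resid, n_events, residence_time
#'   (survival-fit 1/koff, ns), mean_duration, max_duration,
#'   occupancy_fraction (union over lipids of contacted time / total_time).
#' @export
residue_residence_times <- function(events, total_time = NULL) {
  total_time <- total_time %||% attr(events, "total_time")
  if (is.null(total_time) || total_time <= 0) stop("total_time must be positive")
  residues <- attr(events, "residues")
  if (is.null(residues)) {
    residues <- unique(events[, c("chain", "resid")])
  }
  out <- residues[, c("chain", "resid"), drop = FALSE]
  out$n_events <- 0L
  out$residence_time <- 0
  out$mean_duration <- 0
  out$max_duration <- 0
  out$occupancy_fraction <- 0
  if (nrow(events)) {
    key_e <- paste(events$chain, events$resid, sep = "\r")
    key_r <- paste(out$chain, out$resid, sep = "\r")
    for (i in seq_len(nrow(out))) {
      e <- events[key_e == key_r[i], , drop = FALSE]
      if (!nrow(e)) next
      dur <- e$end - e$start
      out$n_events[i] <- nrow(e)
      out$residence_time[i] <- fit_residence_time(dur)
      out$mean_duration[i] <- mean(dur)
      out$max_duration[i] <- max(dur)
      out$occupancy_fraction[i] <-
        min(1, interval_union_length(e$start, e$end) / total_time)
    }
  }
  rownames(out) <- NULL
  out
}

#' Cluster contacted residues into binding sites
#'
#' Builds a residue graph: edge (i, j) when, among frames where either
#' residue contacts some lipid, the same lipid contacts both in at least
#' `co_occurrence_min` of those frames. Connected components with >= 2
#' residues become sites. A site-level event is a maximal run of frames in
#' which one lipid contacts >= 2 site residues simultaneously; the site
#' residence time is fitted from those event durations. Sites are ordered
#' by descending residence time, ties by smallest residue number. Sites
#' with residence time >= `flag_ns` carry `long_lived = TRUE` (a reporting
#' flag only; the site list is unaffected).
#'
#' @param events Event data.frame from [detect_contacts()].
#' @param co_occurrence_min Co-occurrence fraction for an edge (default 0.5).
#' @param flag_ns Long-lived reporting threshold in ns (default 3000).
#' @return List of `BindingSite` objects (class `binding_site_list`), each
#'   with residues, residence_time, mean/max duration, occupancy_fraction,
#'   events, representative pose and `long_lived` flag.
#' @export
cluster_sites <- function(events, co_occurrence_min = 0.5, flag_ns = 3000) {
  if (!nrow(events)) stop("no contact events to cluster")
  times <- attr(events, "times")
  dt <- attr(events, "dt") %||% 1
  if (is.null(times)) stop("events lack the frame-time attribute from detect_contacts()")
  nf <- length(times)
  residues <- unique(events[, c("chain", "resid")])
  residues <- residues[order(residues$chain, residues$resid), , drop = FALSE]
  nr <- nrow(residues)
  lipids <- sort(unique(events$lipid_id))
  key_r <- paste(residues$chain, residues$resid, sep = "\r")
  key_e <- paste(events$chain, events$resid, sep = "\r")
  ridx <- match(key_e, key_r)
  lidx <- match(events$lipid_id, lipids)
  # per-lipid residue x frame contact booleans
  B <- lapply(seq_along(lipids), function(l) matrix(FALSE, nr, nf))
  for (k in seq_len(nrow(events))) {
    B[[lidx[k]]][ridx[k], events$start_frame[k]:events$end_frame[k]] <- TRUE
  }
  any_contact <- Reduce(`|`, B)
  # co-occurrence graph
  adj <- matrix(FALSE, nr, nr)
  if (nr > 1) for (i in 1:(nr - 1)) for (j in (i + 1):nr) {
    denom <- any_contact[i, ] | any_contact[j, ]
    nd <- sum(denom)
    if (nd == 0) next
    both <- rep(FALSE, nf)
    for (l in seq_along(lipids)) both <- both | (B[[l]][i, ] & B[[l]][j, ])
    if (sum(both) / nd >= co_occurrence_min) adj[i, j] <- adj[j, i] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sites <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    # site-level events: lipid touches >= 2 member residues simultaneously
    sev <- list()
    for (l in seq_along(lipids)) {
      multi <- colSums(B[[l]][members, , drop = FALSE]) >= 2L
      r <- rle(multi)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        sev[[length(sev) + 1L]] <- data.frame(
          lipid_id = lipids[l], start_frame = starts[k], end_frame = ends[k])
      }
    }
    if (!length(sev)) next
    sev <- do.call(rbind, sev)
    sev$start <- times[sev$start_frame]
    sev$end <- times[sev$end_frame] + dt
    dur <- sev$end - sev$start
    # representative pose: midpoint frame of the longest event, earliest tie
    best <- which(dur == max(dur))
    best <- best[which.min(sev$start_frame[best])]
    rep_frame <- as.integer(floor((sev$start_frame[best] + sev$end_frame[best]) / 2))
    multi_any <- rep(FALSE, nf)
    for (l in seq_along(lipids))
      multi_any <- multi_any | (colSums(B[[l]][members, , drop = FALSE]) >= 2L)
    rt <- fit_residence_time(dur)
    sites[[length(sites) + 1L]] <- structure(list(
      residues = residues[members, , drop = FALSE],
      residence_time = rt,
      mean_duration = mean(dur),
      max_duration = max(dur),
      occupancy_fraction = mean(multi_any),
      n_events = nrow(sev),
      events = sev,
      representative_pose = list(frame = rep_frame,
                                 lipid_id = sev$lipid_id[best]),
      long_lived = rt >= flag_ns
    ), class = "BindingSite")
  }
  if (length(sites)) {
    rt <- vapply(sites, `[[`, numeric(1), "residence_time")
    minres <- vapply(sites, function(s) min(s$residues$resid), numeric(1))
    sites <- sites[order(-rt, minres)]
  }
  structure(sites, class = "binding_site_list")
}

#' @export
print.BindingSite <- function(x, ...) {
  cat("BindingSite:", paste0(x$residues$chain, ":", x$residues$resid,
                             collapse = ", "),
      sprintf("| residence %.3g ns, max %.3g ns, occupancy %.2f%s",
              x$residence_time, x$max_duration, x$occupancy_fraction,
              if (x$long_lived) " [long-lived]" else ""), "\n")
  invisible(x)
}

#' @export
print.binding_site_list <- function(x, ...) {
  cat(length(x), "binding site(s)\n")
  for (s in x) print(s)
  invisible(x)
}

#' Summarize a binding-site list as a data.frame
#' @param x A `binding_site_list`.
#' @param ... Unused.
#' @return data.frame with one row per site.
#' @export
as.data.frame.binding_site_list <- function(x, ...) {
  if (!length(x)) return(data.frame(site = integer(0)))
  do.call(rbind, lapply(seq_along(x), function(i) {
    s <- x[[i]]
    data.frame(site = i,
               residues = paste0(s$residues$chain, ":", s$residues$resid,
                                 collapse = "+"),
               residence_time = s$residence_time,
               mean_duration = s$mean_duration,
               max_duration = s$max_duration,
               occupancy_fraction = s$occupancy_fraction,
               n_events = s$n_events,
               pose_frame = s$representative_pose$frame,
               pose_lipid = s$representative_pose$lipid_id,
               long_lived = s$long_lived,
               stringsAsFactors = FALSE)
  }))
}

#' Representative pose of a binding site
#'
#' The midpoint frame of the longest site-level event and the lipid
#' involved (earliest event on ties).
#'
#' @param site A `BindingSite`.
#' @param traj Optional `Trajectory` for bounds checking.
#' @return List with `frame` (index) and `lipid_id`.
#' @export
representative_pose <- function(site, traj = NULL) {
  stopifnot(inherits(site, "BindingSite"))
  if (is.null(site$events) || !nrow(site$events))
    stop("site has no qualifying events")
  rp <- site$representative_pose
  if (!is.null(traj) && (rp$frame < 1 || rp$frame > n_frames(traj)))
    stop("representative frame outside trajectory")
  rp
}
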