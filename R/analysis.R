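#' Detect aneurysm entry/exit events in a cell track
#'
#' A *passage* is one traversal of the neck-adjacent parent segment
#' (the x-interval spanned by the neck, widened by one parent width); a cell
#' recirculating through the periodic channel accrues one passage per
#' traversal. The cell *entered* the aneurysm when its centre of mass is
#' classified in the body lumen for at least `debounce` consecutive frames;
#' the residence time runs from the first to the last frame of the maximal
#' body-resident run. Cells still inside at the end of the track are
#' censored. Cells born inside the aneurysm are excluded.
#'
#' @param track data frame for one cell (columns `time`, `x`, `region`,
#'   optionally `born_inside`), frames in order
#' @param g the channel geometry the track was recorded in
#' @param debounce minimum consecutive body-resident frames (default 3)
#' @return data frame of passage records: `passage`, `t_pass`, `entered`,
#'   `t_enter`, `t_exit`, `residence` (completed events only), `observed`
#'   (in-body duration including the lower-bound time of censored events)
#'   and `censored`
#' @export
detect_events <- function(track, g, debounce = 3) {
  empty <- data.frame(passage = integer(0), t_pass = numeric(0),
                      entered = logical(0), t_enter = numeric(0),
                      t_exit = numeric(0), residence = numeric(0),
                      observed = numeric(0), censored = logical(0))
  if (is.null(track) || nrow(track) < 2) return(empty)
  if (isTRUE(track$born_inside[1])) return(empty)
  reg <- track$region
  tt <- track$time
  # --- body-resident runs (debounced) ---
  inside <- reg == "ma_body"
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= debounce)
  events <- data.frame(t_enter = tt[starts[runs]], t_exit = tt[ends[runs]],
                       censored = ends[runs] == length(inside))
  # --- passages through the neck segment of the parent duct ---
  x0 <- g$xc - g$h - g$r2
  x1 <- g$xc + g$h + g$r2
  inseg <- (track$x >= x0 & track$x <= x1) | inside
  rs <- rle(inseg)
  seg_runs <- which(rs$values)
  n_pass <- length(seg_runs)
  if (n_pass == 0) return(empty)
  seg_ends <- cumsum(rs$lengths)
  seg_starts <- seg_ends - rs$lengths + 1
  out <- data.frame(passage = seq_len(n_pass),
                    t_pass = tt[seg_starts[seg_runs]],
                    entered = FALSE, t_enter = NA_real_, t_exit = NA_real_,
                    residence = NA_real_, observed = NA_real_,
                    censored = FALSE)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      # attach each entry to the passage whose segment window contains it
      w <- which(tt[seg_starts[seg_runs]] <= events$t_enter[k] &
                   tt[seg_ends[seg_runs]] >= events$t_enter[k])
      if (!length(w)) w <- n_pass
      w <- w[1]
      out$entered[w] <- TRUE
      out$t_enter[w] <- events$t_enter[k]
      # observed in-body duration: equals the residence for completed
      # events, and the (lower-bound) time observed inside for censored ones
      out$observed[w] <- events$t_exit[k] - events$t_enter[k]
      if (!events$censored[k]) {
        out$t_exit[w] <- events$t_exit[k]
        out$residence[w] <- events$t_exit[k] - events$t_enter[k]
      } else {
        out$censored[w] <- TRUE
      }
    }
  }
  out
}

#' Events for every cell of a run
#'
#' @param tracks the `tracks` data frame of a [run_simulation()] result
#' @param g the channel geometry
#' @param debounce see [detect_events()]
#' @return combined passage records with `cell` and `type` columns
#' @export
detect_all_events <- function(tracks, g, debounce = 3) {
  out <- lapply(split(tracks, tracks$cell), function(tr) {
    ev <- detect_events(tr[order(tr$frame), ], g, debounce)
    if (nrow(ev)) {
      ev$cell <- tr$cell[1]
      ev$type <- tr$type[1]
    }
    ev
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Aneurysm entry probability per passage
#'
#' Point estimate `n_entries / n_passages` with a nonparametric bootstrap
#' confidence interval resampled over cells (2000 resamples, seeded).
#'
#' @param records passage records from [detect_all_events()]
#' @param cell_type `"platelet"` or `"rbc"` (NULL: all records)
#' @param n_boot bootstrap resamples
#' @param conf confidence level
#' @param seed bootstrap seed
#' @return list: `probability`, `n_entries`, `n_passages`, `ci`
#' @export
entry_probability <- function(records, cell_type = NULL, n_boot = 2000,
                              conf = 0.95, seed = 1) {
  if (!is.null(cell_type)) records <- records[records$type == cell_type, ]
  n_pass <- nrow(records)
  if (is.null(records) || n_pass == 0) {
    stop("no passages recorded: entry probability undefined")
  }
  p <- sum(records$entered) / n_pass
  cells <- unique(records$cell)
  ci <- c(NA_real_, NA_real_)
  if (length(cells) > 1) {
    set.seed(seed)
    bp <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(cells, replace = TRUE)
      rr <- do.call(rbind, lapply(pick, function(cc)
        records[records$cell == cc, ]))
      sum(rr$entered) / nrow(rr)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(bp, c(a, 1 - a), na.rm = TRUE))
  }
  list(probability = p, n_entries = sum(records$entered),
       n_passages = n_pass, ci = ci)
}

#' Residence-time summary
#'
#' Mean and spread of completed (uncensored) residence times; censored
#' events (cells still inside at the end of the run) are counted separately
#' and never mixed into the mean.
#'
#' @inheritParams entry_probability
#' @return list: `mean`, `sd`, `times`, `n_events`, `n_censored`, `ci`
#'   (bootstrap CI of the mean over cells)
#' @export
residence_summary <- function(records, cell_type = NULL, n_boot = 2000,
                              conf = 0.95, seed = 1) {
  if (!is.null(cell_type)) records <- records[records$type == cell_type, ]
  ev <- records[records$entered & !records$censored &
                  is.finite(records$residence), ]
  ncen <- sum(records$censored)
  if (nrow(ev) == 0) {
    if (ncen > 0) {
      return(list(mean = NA_real_, sd = NA_real_, times = numeric(0),
                  n_events = 0L, n_censored = ncen, ci = c(NA, NA),
                  status = "censored-only"))
    }
    stop("no completed entry events")
  }
  cells <- unique(ev$cell)
  ci <- c(NA_real_, NA_real_)
  if (length(cells) > 1) {
    set.seed(seed)
    bm <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(cells, replace = TRUE)
      mean(unlist(lapply(pick, function(cc)
        ev$residence[ev$cell == cc])))
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(bm, c(a, 1 - a), na.rm = TRUE))
  }
  list(mean = mean(ev$residence), sd = sd(ev$residence),
       times = ev$residence, n_events = nrow(ev), n_censored = ncen,
       ci = ci, status = "ok")
}

#' Perfusion map of the aneurysm body
#'
#' Voxelises the body lumen and marks voxels visited by the centre of mass
#' of red cells that originated in the parent vessel. The perfused fraction
#' (occupied body voxels over total body voxels) operationalises how far
#' the through-flowing blood reaches into the aneurysm; it is a summary
#' invented for this package, reported as such.
#'
#' @param tracks tracks data frame (red cells born in the parent are used)
#' @param g channel geometry
#' @param voxel voxel edge length, um (must not exceed the body diameter)
#' @return list: `fraction`, `occupied`, `total`, and the occupancy array
#'   coordinates
#' @export
perfusion_map <- function(tracks, g, voxel = 2) {
  if (voxel > g$R1) stop("voxel size exceeds the body diameter")
  tr <- tracks[tracks$type == "rbc" & !tracks$born_inside, , drop = FALSE]
  xs <- seq(g$xc - g$R, g$xc + g$R, by = voxel)
  ys <- seq(g$r2, g$yc + g$R, by = voxel)
  zs <- seq(0, g$depth, by = voxel)
  cen <- as.matrix(expand.grid(x = xs + voxel / 2, y = ys + voxel / 2,
                               z = zs + voxel / 2))
  body <- cpp_classify_points(geometry_vec(g), cen) == 2L
  total <- sum(body)
  occ <- rep(FALSE, nrow(cen))
  inb <- tr[tr$region == "ma_body", , drop = FALSE]
  if (nrow(inb)) {
    ix <- floor((inb$x - (g$xc - g$R)) / voxel)
    iy <- floor((inb$y - g$r2) / voxel)
    iz <- floor((inb$z - 0) / voxel)
    nx <- length(xs); ny <- length(ys)
    valid <- ix >= 0 & ix < nx & iy >= 0 & iy < length(ys) & iz >= 0 &
      iz < length(zs)
    key <- 1 + ix[valid] + nx * (iy[valid] + ny * iz[valid])
    occ[unique(key)] <- TRUE
  }
  list(fraction = if (total > 0) sum(occ & body) / total else NA_real_,
       occupied = sum(occ & body), total = total,
       centers = cen[body, , drop = FALSE],
       visited = occ[body])
}

#' Transport metrics of a run
#'
#' Convenience wrapper: detects events and reports entry probability and
#' residence summaries per cell type.
#'
#' @param result a [run_simulation()] result
#' @param debounce see [detect_events()]
#' @return list with `records`, `platelet`, `rbc` metric slices
#' @export
transport_metrics <- function(result, debounce = 3) {
  g <- result$config$geometry
  rec <- detect_all_events(result$tracks, g, debounce)
  slice <- function(type) {
    if (is.null(rec) || !any(rec$type == type)) return(NULL)
    list(
      entry = tryCatch(entry_probability(rec, type), error = function(e) NULL),
      residence = tryCatch(residence_summary(rec, type),
                           error = function(e) NULL))
  }
  list(records = rec, platelet = slice("platelet"), rbc = slice("rbc"))
}
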