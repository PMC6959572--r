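# Shared fixtures and independent oracles. Expensive cohorts are
# memoised so several test files (and the acceptance checks) reuse one
# computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# --- engulfment cohort: 26 ROIs per arm at default densities ----------
# Arms mirror the study conditions: control engulfment rate 0.30 and a
# 2.3-fold overexpression arm at 0.69.
engulfment_cohort <- function() {
  memo("engulfment_cohort", function() {
    rates <- c(control = 0.30, overexpression = 0.69)
    rows <- vector("list", 52L)
    for (arm_i in seq_along(rates)) {
      for (k in 1:26) {
        seed <- (arm_i - 1L) * 26L + k
        p <- engulfment_scene_params(engulfment_rate = rates[[arm_i]],
                                     seed = seed)
        g <- generate_engulfment_stack(p)
        cells <- microglia_cells_from_truth(g$truth)
        nl <- shifted_null(g$stack, cells, n_rounds = 2L,
                           seed = 1000L + seed)
        rows[[seed]] <- data.frame(
          arm = names(rates)[arm_i], seed = seed,
          truth_pct = 100 * mean(vapply(g$truth$cells, `[[`, TRUE,
                                        "engulfed")),
          obs_pct = nl$observed$summary$pct_positive,
          null_pct = nl$mean_null_pct_positive,
          n_cells = nl$observed$summary$n_microglia)
      }
    }
    do.call(rbind, rows)
  })
}

# --- spine cohort: 400 protrusions, tri-modal volume mixture ----------
spine_cohort <- function() {
  memo("spine_cohort", function() {
    g <- generate_spine_image(400, seed = 2)
    m <- measure_protrusions(g$stack, g$truth$protrusions,
                             g$truth$shaft_masks)
    list(gen = g, measured = m,
         truth_class = vapply(g$truth$protrusions, `[[`, "", "klass"),
         truth_volume = vapply(g$truth$protrusions, `[[`, 0,
                               "volume_um3"))
  })
}

# --- ExM cohort: matched pre/post pairs at linear factor 2.8 ----------
# Pairs are analyzed as they are generated and only summaries are kept
# (a full pair of rendered stacks is ~0.3 GB). The first pair's CD68
# channel and one cell mask are retained for the scale-invariance
# check.
exm_results <- function(n_pairs = 4L) {
  memo("exm_results", function() {
    cells <- list(); keep <- NULL; truth_axes1 <- NULL
    for (s in seq_len(n_pairs)) {
      pair <- generate_exm_pair(2.8, seed = 40 + s,
        scene = engulfment_scene_params(roi_size_um = c(70, 70),
                                        n_microglia = 2L,
                                        free_puncta_density = 0.05,
                                        engulfment_rate = 0.8))
      geom <- stack_geometry(pair$post$stack)
      cd <- get_channel(pair$post$stack, "CD68")
      psd <- get_channel(pair$post$stack, "PSD95")
      ny <- dim(cd)[1L]
      for (i in seq_along(pair$post$truth$cells)) {
        pre_cl <- pair$pre$truth$cells[[i]]
        post_cl <- pair$post$truth$cells[[i]]
        pre_ax <- measure_soma_axes(pair$pre$stack,
                                    pre_cl$soma_center_um)
        post_ax <- measure_soma_axes(pair$post$stack,
                                     post_cl$soma_center_um)
        m <- matrix(FALSE, ny, dim(cd)[2L]); m[post_cl$mask_idx] <- TRUE
        lys <- detect_lysosomes(cd, m, geom)
        allidx <- unlist(lapply(lys, `[[`, "roi_idx"))
        pos <- vapply(lys, function(l)
          score_psd_positive(l, psd, cd, allidx)$positive, logical(1))
        cells[[length(cells) + 1L]] <- list(
          factor = scaling_factor(pre_ax, post_ax)$factor,
          pre_axes = pre_ax, post_axes = post_ax,
          lysosome_sizes = vapply(lys, `[[`, 0, "area_um2_expanded"),
          n_detected = length(lys), positive = pos,
          truth = post_cl$lysosomes)
      }
      if (s == 1L) {
        truth_axes1 <- pair$truth$soma_axes
        cl1 <- pair$post$truth$cells[[1L]]
        keep <- list(cd = cd, mask_idx = cl1$mask_idx, geom = geom,
                     dim = dim(cd)[1:2])
      }
    }
    list(cells = cells, invariance = keep, truth_axes1 = truth_axes1)
  })
}

# --- leaky integrate-and-fire simulator (independent F-I oracle) ------
# Analytic rheobase for a step of duration T:
#   I* = (Vth - EL) / (R * (1 - exp(-T / tau)))
simulate_lif_sweep <- function(I_pA, fs = 10000, dur_s = 0.3,
                               pre_s = 0.05, post_s = 0.05, tau = 0.02,
                               R_MOhm = 100, EL = -70, Vth = -50,
                               Vreset = -65) {
  n_pre <- round(pre_s * fs); n_step <- round(dur_s * fs)
  n <- n_pre + n_step + round(post_s * fs)
  v <- numeric(n); v[1] <- EL
  i <- 2L
  while (i <= n) {
    I <- if (i > n_pre && i <= n_pre + n_step) I_pA else 0
    v[i] <- v[i - 1L] + ((EL - v[i - 1L]) + I * R_MOhm * 1e-3) / tau / fs
    if (v[i] >= Vth) {
      n_up <- round(0.0003 * fs); n_dn <- round(0.0007 * fs)
      wave <- c(seq(Vth, 30, length.out = n_up + 1L)[-1L],
                seq(30, Vreset, length.out = n_dn + 1L)[-1L])
      j <- min(n, i + length(wave) - 1L)
      v[i:j] <- wave[seq_len(j - i + 1L)]
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  sweep_trace(v, fs, "current_clamp", step_pA = I_pA,
              step_window = c(n_pre + 1L, n_pre + n_step))
}

lif_analytic_rheobase <- function(dur_s = 0.3, tau = 0.02, R_MOhm = 100,
                                  EL = -70, Vth = -50) {
  (Vth - EL) / (R_MOhm * 1e-3 * (1 - exp(-dur_s / tau)))
}

# --- brute-force flood fill (independent labeling oracle) -------------
flood_fill_count <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  seen <- matrix(FALSE, ny, nx)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    o <- expand.grid(di = -1:1, dj = -1:1)
    o <- o[!(o$di == 0 & o$dj == 0), ]
    split(as.matrix(o), seq_len(nrow(o)))
  }
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      ci <- (cur - 1L) %% ny + 1L; cj <- (cur - 1L) %/% ny + 1L
      for (o in offs) {
        ii <- ci + o[[1L]]; jj <- cj + o[[2L]]
        if (ii >= 1L && ii <= ny && jj >= 1L && jj <= nx &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, ii + (jj - 1L) * ny)
        }
      }
    }
  }
  count
}

# --- dense-sampling Sholl oracle --------------------------------------
# Samples every internode segment at `step_um` and counts sign changes
# of (distance-to-soma - r) for every radius.
sholl_oracle <- function(tree, radius_step_um = 10, max_radius_um,
                         step_um = 0.1) {
  nd <- tree$nodes
  soma <- c(nd$x[tree$root], nd$y[tree$root], nd$z[tree$root])
  radii <- seq(radius_step_um, max_radius_um, by = radius_step_um)
  counts <- integer(length(radii))
  idmap <- match(nd$parent, nd$id)
  for (i in which(!is.na(idmap) & nd$parent >= 0)) {
    p <- idmap[i]
    a <- c(nd$x[p], nd$y[p], nd$z[p]); b <- c(nd$x[i], nd$y[i], nd$z[i])
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / step_um) + 1L))
    pts <- outer(ts, b - a) + rep(a, each = length(ts))
    d <- sqrt(rowSums((pts - rep(soma, each = length(ts)))^2))
    for (ri in seq_along(radii)) {
      s <- sign(d - radii[ri])
      s[s == 0] <- 1e-9
      counts[ri] <- counts[ri] + sum(abs(diff(s > 0)) > 0)
    }
  }
  counts
}

# Random tree builder for the Sholl property test.
random_tree <- function(seed) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 1, parent = -1L)
  nid <- 1L
  grow <- function(parent_id, depth) {
    px <- nodes$x[nodes$id == parent_id]
    py <- nodes$y[nodes$id == parent_id]
    pz <- nodes$z[nodes$id == parent_id]
    n_child <- if (depth == 0L) sample(1:3, 1L) else
      sample(0:2, 1L, prob = c(0.4, 0.35, 0.25))
    for (k in seq_len(n_child)) {
      ang <- runif(1, 0, 2 * pi); elev <- runif(1, -0.5, 0.5)
      len <- runif(1, 8, 35)
      nid <<- nid + 1L
      nodes <<- rbind(nodes, data.frame(
        id = nid, type = 3L,
        x = px + len * cos(ang) * cos(elev),
        y = py + len * sin(ang) * cos(elev),
        z = pz + len * sin(elev), radius = 0.5, parent = parent_id))
      if (depth < 3L) grow(nid, depth + 1L)
    }
  }
  grow(1L, 0L)
  neuron_tree(nodes)
}
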