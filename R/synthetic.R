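#' Type template for the synthetic-morphology generator
#'
#' A template encodes the qualitative, type-specific contrasts the
#' classification pipeline must recover: ascending translaminar Martinotti
#' axons, local basket arbors with sharp remote angles and many dendritic
#' stems, radially narrow bipolar double-bouquet cells, short vertical
#' chandelier terminals. The generator makes no claim of biological realism
#' beyond these controllable summary statistics.
#'
#' @param type_name Type label.
#' @param axon List: `n_terminals`, `branch_length_mean`/`_sd` (micrometers,
#'   lognormal), `angle_mean`/`angle_sd` (remote bifurcation angle, degrees),
#'   `drift` (radial direction bias per bifurcation; positive = toward pia),
#'   `vertical_terminals` (force short vertical terminal branches).
#' @param dendrite List: `n_stems`, `polarity` (`"multipolar"` or
#'   `"bipolar"`), `stem_terminals`, `branch_length_mean`/`_sd`,
#'   `angle_mean`/`angle_sd`, `drift` (radial bias along each stem's axis).
#' @param home_layers Named probability vector over layer names.
#' @return A `type_template`.
#' @export
type_template <- function(type_name, axon, dendrite,
                          home_layers = c("L2/3" = 0.4, "L4" = 0.3, "L5" = 0.3)) {
  ax <- utils::modifyList(list(
    n_terminals = 40L, branch_length_mean = 60, branch_length_sd = 35,
    angle_mean = 70, angle_sd = 25, drift = 0, vertical_terminals = FALSE), axon)
  de <- utils::modifyList(list(
    n_stems = 5L, polarity = "multipolar", stem_terminals = 4L,
    branch_length_mean = 45, branch_length_sd = 25,
    angle_mean = 60, angle_sd = 25, drift = 0), dendrite)
  stopifnot(ax$branch_length_mean > 0, ax$branch_length_sd > 0,
            de$branch_length_mean > 0, ax$n_terminals >= 1,
            de$polarity %in% c("multipolar", "bipolar"),
            abs(sum(home_layers) - 1) < 1e-8)
  structure(list(type_name = type_name, axon = ax, dendrite = de,
                 home_layers = home_layers), class = "type_template")
}

#' Default templates for the ten interneuron types
#'
#' Seven base classification types (ChC, BTC, DBC, SBC, NBC, MC, LBC) plus
#' the scarce BP and NGC types used only by cohort-exclusion fixtures.
#'
#' @return Named list of [type_template()] objects.
#' @export
default_templates <- function() {
  list(
    MC = type_template("MC",
      axon = list(n_terminals = 45L, branch_length_mean = 90,
                  branch_length_sd = 50, angle_mean = 82, angle_sd = 22,
                  drift = 0.7),
      dendrite = list(n_stems = 2L, polarity = "bipolar", stem_terminals = 5L,
                      branch_length_mean = 55, branch_length_sd = 25,
                      drift = 0.35),
      home_layers = c("L2/3" = 0.3, "L4" = 0.2, "L5" = 0.3, "L6" = 0.2)),
    ChC = type_template("ChC",
      axon = list(n_terminals = 55L, branch_length_mean = 40,
                  branch_length_sd = 18, angle_mean = 68, angle_sd = 22,
                  drift = 0, vertical_terminals = TRUE),
      dendrite = list(n_stems = 5L, polarity = "multipolar",
                      stem_terminals = 3L, branch_length_mean = 40,
                      branch_length_sd = 18),
      home_layers = c("L2/3" = 0.6, "L4" = 0.2, "L5" = 0.2)),
    NBC = type_template("NBC",
      axon = list(n_terminals = 45L, branch_length_mean = 55,
                  branch_length_sd = 28, angle_mean = 55, angle_sd = 18,
                  drift = 0),
      dendrite = list(n_stems = 7L, polarity = "multipolar",
                      stem_terminals = 3L, branch_length_mean = 40,
                      branch_length_sd = 18),
      home_layers = c("L2/3" = 0.4, "L4" = 0.3, "L5" = 0.3)),
    LBC = type_template("LBC",
      axon = list(n_terminals = 50L, branch_length_mean = 75,
                  branch_length_sd = 45, angle_mean = 50, angle_sd = 16,
                  drift = 0),
      dendrite = list(n_stems = 8L, polarity = "multipolar",
                      stem_terminals = 3L, branch_length_mean = 45,
                      branch_length_sd = 20),
      home_layers = c("L2/3" = 0.3, "L4" = 0.2, "L5" = 0.3, "L6" = 0.2)),
    SBC = type_template("SBC",
      axon = list(n_terminals = 70L, branch_length_mean = 35,
                  branch_length_sd = 15, angle_mean = 58, angle_sd = 18,
                  drift = 0),
      dendrite = list(n_stems = 6L, polarity = "multipolar",
                      stem_terminals = 3L, branch_length_mean = 35,
                      branch_length_sd = 15),
      home_layers = c("L2/3" = 0.4, "L4" = 0.4, "L5" = 0.2)),
    DBC = type_template("DBC",
      axon = list(n_terminals = 45L, branch_length_mean = 50,
                  branch_length_sd = 28, angle_mean = 62, angle_sd = 20,
                  drift = -0.45),
      dendrite = list(n_stems = 2L, polarity = "bipolar", stem_terminals = 4L,
                      branch_length_mean = 50, branch_length_sd = 22,
                      drift = 0.35),
      home_layers = c("L2/3" = 0.5, "L4" = 0.3, "L5" = 0.2)),
    BTC = type_template("BTC",
      axon = list(n_terminals = 45L, branch_length_mean = 50,
                  branch_length_sd = 25, angle_mean = 74, angle_sd = 24,
                  drift = 0.15),
      dendrite = list(n_stems = 2L, polarity = "bipolar", stem_terminals = 5L,
                      branch_length_mean = 50, branch_length_sd = 22,
                      drift = 0.3),
      home_layers = c("L2/3" = 0.4, "L4" = 0.3, "L5" = 0.3)),
    BP = type_template("BP",
      axon = list(n_terminals = 45L, branch_length_mean = 50,
                  branch_length_sd = 25, angle_mean = 66, angle_sd = 22,
                  drift = 0.3),
      dendrite = list(n_stems = 2L, polarity = "bipolar", stem_terminals = 3L,
                      branch_length_mean = 45, branch_length_sd = 20,
                      drift = 0.3),
      home_layers = c("L2/3" = 0.5, "L4" = 0.3, "L5" = 0.2)),
    NGC = type_template("NGC",
      axon = list(n_terminals = 100L, branch_length_mean = 25,
                  branch_length_sd = 10, angle_mean = 75, angle_sd = 24,
                  drift = 0),
      dendrite = list(n_stems = 6L, polarity = "multipolar",
                      stem_terminals = 3L, branch_length_mean = 30,
                      branch_length_sd = 12),
      home_layers = c("L2/3" = 0.4, "L4" = 0.3, "L5" = 0.3)))
}

# Rodrigues rotation of vector v about unit axis k by `deg` degrees.
rotate_about <- function(v, k, deg) {
  th <- deg * pi / 180
  v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                  k[3] * v[1] - k[1] * v[3],
                  k[1] * v[2] - k[2] * v[1]) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 1, 0) else v / n
}

# Random unit axis perpendicular to dir.
perp_axis <- function(dir) {
  repeat {
    r <- stats::rnorm(3)
    ax <- c(dir[2] * r[3] - dir[3] * r[2],
            dir[3] * r[1] - dir[1] * r[3],
            dir[1] * r[2] - dir[2] * r[1])
    n <- sqrt(sum(ax^2))
    if (n > 1e-6) return(ax / n)
  }
}

# Grow one arbor: recursive binary branching with straight 2-um-step
# branches. Remote bifurcation angles are exact Gaussian draws because
# branches are straight and the radial drift is applied to the parent
# direction before the children are rotated apart.
grow_arbor <- function(env, attach_id, start_pos, dir, tips, params,
                       step = 2) {
  meanlog <- log(params$branch_length_mean^2 /
                 sqrt(params$branch_length_sd^2 + params$branch_length_mean^2))
  sdlog <- sqrt(log(1 + params$branch_length_sd^2 /
                    params$branch_length_mean^2))
  recurse <- function(attach_id, pos, dir, tips) {
    terminal <- tips == 1L
    if (terminal && isTRUE(params$vertical_terminals)) {
      dir <- unitize(c(stats::rnorm(1, 0, 0.15),
                       sample(c(-1, 1), 1),
                       stats::rnorm(1, 0, 0.15)))
      len <- stats::runif(1, 15, 40)
    } else {
      len <- stats::rlnorm(1, meanlog, sdlog)
      len <- min(max(len, 2 * step), 6 * params$branch_length_mean)
    }
    n_steps <- max(1L, as.integer(round(len / step)))
    ts <- seq_len(n_steps) * step
    ids <- env$n + seq_len(n_steps)
    env$branches[[length(env$branches) + 1L]] <- list(
      x = pos[1] + dir[1] * ts, y = pos[2] + dir[2] * ts,
      z = pos[3] + dir[3] * ts,
      parent = c(attach_id, ids[-n_steps]),
      type = rep(params$swc_type, n_steps))
    env$n <- env$n + n_steps
    prev <- ids[n_steps]
    if (!terminal) {
      end_pos <- pos + dir * (n_steps * step)
      a <- min(max(stats::rnorm(1, params$angle_mean, params$angle_sd), 10), 170)
      w <- stats::runif(1, 0.35, 0.65)
      dir_eff <- unitize(dir + c(0, params$drift, 0))
      ax <- perp_axis(dir_eff)
      d1 <- rotate_about(dir_eff, ax, a * w)
      d2 <- rotate_about(dir_eff, ax, -a * (1 - w))
      l <- sample.int(tips - 1L, 1L)
      recurse(prev, end_pos, d1, l)
      recurse(prev, end_pos, d2, tips - l)
    }
  }
  recurse(attach_id, start_pos, dir, tips)
}

#' Generate one synthetic neuron
#'
#' Deterministic for a given seed and template: identical calls yield
#' bit-identical node tables. The neuron is returned centered at the soma
#' (a single soma point at the origin) with its home layer drawn from the
#' template's laminar distribution.
#'
#' @param template A [type_template()].
#' @param seed Integer seed.
#' @param cell_id Cell identifier.
#' @return A centered [neuron()].
#' @export
generate_neuron <- function(template, seed, cell_id = NULL) {
  stopifnot(inherits(template, "type_template"))
  if (template$axon$branch_length_mean <= 0) stop("degenerate template")
  cell_id <- cell_id %||% sprintf("%s_seed%d", template$type_name, seed)
  with_seed(seed, {
    env <- new.env()
    env$branches <- list(list(x = 0, y = 0, z = 0, parent = -1L,
                              type = 1L))     # soma point
    env$n <- 1L
    soma_r <- 8

    # axon: origin biased toward the drift direction (ascending axons
    # emerge from the upper part of the soma)
    ax <- template$axon
    ax$swc_type <- 2L
    dir0 <- unitize(c(stats::rnorm(1, 0, 0.5),
                      ax$drift * 2 + stats::rnorm(1, 0, 0.5),
                      stats::rnorm(1, 0, 0.5)))
    grow_arbor(env, 1L, dir0 * soma_r, dir0, ax$n_terminals, ax)

    # dendrites
    de <- template$dendrite
    de$swc_type <- 3L
    if (de$polarity == "bipolar") {
      stem_dirs <- lapply(c(1, -1), function(s)
        unitize(c(stats::rnorm(1, 0, 0.12), s, stats::rnorm(1, 0, 0.12))))
    } else {
      stem_dirs <- lapply(seq_len(de$n_stems), function(i)
        unitize(c(stats::rnorm(1), stats::rnorm(1), 0.5 * stats::rnorm(1))))
    }
    for (d0 in stem_dirs) {
      dd <- de
      dd$drift <- de$drift * sign(d0[2])
      grow_arbor(env, 1L, d0 * soma_r, d0, de$stem_terminals, dd)
    }

    n <- env$n
    nodes <- data.frame(
      id = seq_len(n),
      type = unlist(lapply(env$branches, `[[`, "type")),
      x = unlist(lapply(env$branches, `[[`, "x")),
      y = unlist(lapply(env$branches, `[[`, "y")),
      z = unlist(lapply(env$branches, `[[`, "z")),
      radius = c(soma_r, rep(0.4, n - 1L)),
      parent = as.integer(unlist(lapply(env$branches, `[[`, "parent"))))
    home <- sample(names(template$home_layers), 1,
                   prob = template$home_layers)
    center_at_soma(neuron(nodes, cell_id = cell_id, home_layer = home,
                          label = template$type_name))
  })
}

#' Inject a reconstruction defect into a neuron
#'
#' Produces a modified copy guaranteed to trigger the corresponding QC flag
#' under default thresholds.
#'
#' @param x A [neuron()] with an axon.
#' @param defect One of `"interrupted_axon"`, `"short_axon"`,
#'   `"long_segment"`, `"flat_arbor"`.
#' @param seed Integer seed for the choice of affected node.
#' @return The modified neuron.
#' @export
inject_defects <- function(x, defect, seed = 1) {
  stopifnot(inherits(x, "neuron"))
  defect <- match.arg(defect, c("interrupted_axon", "short_axon",
                                "long_segment", "flat_arbor"))
  nd <- x$nodes
  ax <- which(nd$type == "axon")
  if (length(ax) == 0) stop("neuron ", x$cell_id, " has no axon")
  with_seed(seed, {
    if (defect == "interrupted_axon") {
      # detach a mid-tree axon node with axonal children
      has_kids <- nd$id[ax] %in% nd$parent[ax]
      inner <- ax[has_kids & nd$parent[ax] %in% nd$id[ax]]
      pick <- inner[max(1L, as.integer(length(inner) * stats::runif(1, .4, .6)))]
      nd$parent[pick] <- -1L
    } else if (defect == "short_axon") {
      f <- 2500 / sum(process_segments(x, "axon")$length)
      nd$x[ax] <- nd$x[ax] * f; nd$y[ax] <- nd$y[ax] * f
      nd$z[ax] <- nd$z[ax] * f
    } else if (defect == "long_segment") {
      tips <- ax[!(nd$id[ax] %in% nd$parent)]
      pick <- tips[sample.int(length(tips), 1)]
      pidx <- match(nd$parent[pick], nd$id)
      d <- unitize(c(nd$x[pick] - nd$x[pidx], nd$y[pick] - nd$y[pidx],
                     nd$z[pick] - nd$z[pidx]))
      nd$x[pick] <- nd$x[pidx] + 285 * d[1]
      nd$y[pick] <- nd$y[pidx] + 285 * d[2]
      nd$z[pick] <- nd$z[pidx] + 285 * d[3]
    } else if (defect == "flat_arbor") {
      nd$z[ax] <- nd$z[ax] * 0.05
    }
  })
  x$nodes <- nd
  x
}

#' Cohort specification for the synthetic generator
#'
#' @param counts Named integer vector of per-type cell counts. The default
#'   reproduces the study composition of the eight classified types
#'   (7 ChC, 15 BTC, 22 DBC, 28 SBC, 44 NBC, 50 MC, 51 LBC; 217 cells).
#' @param defects Named integer vector: cells to corrupt with each of
#'   `interrupted_axon`, `short_axon`, `long_segment`, `flat_arbor`.
#' @param seed Master seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(counts = c(ChC = 7, BTC = 15, DBC = 22, SBC = 28,
                                   NBC = 44, MC = 50, LBC = 51),
                        defects = c(interrupted_axon = 0, short_axon = 0,
                                    long_segment = 0, flat_arbor = 0),
                        seed = 1) {
  stopifnot(all(counts >= 0), all(defects >= 0), sum(defects) <= sum(counts))
  def <- c(interrupted_axon = 0, short_axon = 0, long_segment = 0,
           flat_arbor = 0)
  def[names(defects)] <- defects
  structure(list(counts = counts, defects = def, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Generates `counts[t]` neurons per type and injects the requested defects
#' into randomly chosen cells (disjoint across defect kinds), all under the
#' spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @param templates Named list of [type_template()]s.
#' @param thresholds [qc_thresholds()] for the roster's QC reports.
#' @return A [cohort_roster()]; the injected defects are recorded in the
#'   `defect_log` attribute (cell_id, defect).
#' @export
generate_cohort <- function(spec, templates = default_templates(),
                            thresholds = qc_thresholds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  unknown <- setdiff(names(spec$counts), names(templates))
  if (length(unknown) > 0) {
    stop("no template registered for type(s): ", paste(unknown, collapse = ", "))
  }
  neurons <- list()
  i <- 0L
  for (tp in names(spec$counts)) {
    for (k in seq_len(spec$counts[[tp]])) {
      i <- i + 1L
      neurons[[i]] <- generate_neuron(templates[[tp]],
                                      seed = derive_seed(spec$seed, i),
                                      cell_id = sprintf("%s_%03d", tp, k))
    }
  }
  defect_log <- data.frame(cell_id = character(0), defect = character(0))
  if (sum(spec$defects) > 0 && length(neurons) > 0) {
    picks <- with_seed(derive_seed(spec$seed, 0L),
                       sample.int(length(neurons), sum(spec$defects)))
    j <- 0L
    for (d in names(spec$defects)) {
      for (k in seq_len(spec$defects[[d]])) {
        j <- j + 1L
        idx <- picks[j]
        neurons[[idx]] <- inject_defects(neurons[[idx]], d,
                                         seed = derive_seed(spec$seed, 10000L + j))
        defect_log <- rbind(defect_log,
                            data.frame(cell_id = neurons[[idx]]$cell_id,
                                       defect = d))
      }
    }
  }
  roster <- cohort_roster(neurons, thresholds = thresholds)
  attr(roster, "defect_log") <- defect_log
  roster
}
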