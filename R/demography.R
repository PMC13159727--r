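#' @useDynLib rhinopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize quantile rbinom rbeta runif setNames
#' @importFrom utils read.table write.table head modifyList
NULL

.EVENT_KINDS <- c(split = 0L, admixture_pulse = 1L, migration_change = 2L,
                  size_change = 3L)

#' Construct a demographic model as a backward-time event program
#'
#' A demography is a set of demes (each with a diploid effective size and a
#' number of sampled diploid-equivalent haploid lineages) plus an ordered list
#' of backward-time events: population splits (all lineages of \code{source}
#' move into \code{dest} and \code{source} disappears), admixture pulses (a
#' fraction of \code{source} lineages move into \code{dest}), migration-matrix
#' replacements, and size changes. Migration entries are backward
#' per-generation rates: \code{m[d, e]} is the probability per generation that
#' a lineage currently in deme \code{d} traces its ancestry to deme \code{e}.
#'
#' @param demes data.frame with columns \code{label}, \code{Ne} (diploid),
#'   \code{n_samples} (haploid lineages sampled; 0 for unsampled demes).
#' @param events data.frame with columns \code{time} (generations before
#'   present, non-decreasing), \code{kind} (one of \code{split},
#'   \code{admixture_pulse}, \code{migration_change}, \code{size_change}),
#'   \code{source}, \code{dest} (deme labels; \code{dest} ignored for
#'   migration/size changes) and \code{value} (pulse fraction in [0,1], or the
#'   new diploid Ne for size changes; for migration changes, the 1-based index
#'   into \code{mats}).
#' @param migration0 initial (time-0) backward migration matrix, demes x demes;
#'   defaults to no migration.
#' @param mats list of replacement migration matrices referenced by
#'   \code{migration_change} events.
#' @param mu mutation rate per site per generation.
#' @param gen_time_years years per generation (used only for unit conversion).
#' @param check_ancestry if TRUE (default), verify by lineage tracing that the
#'   event program funnels all sampled demes into exactly one ancestral deme.
#' @return an object of class \code{demography}.
#' @export
demography <- function(demes, events = NULL, migration0 = NULL, mats = list(),
                       mu = 1.36e-8, gen_time_years = 10,
                       check_ancestry = TRUE) {
  stopifnot(is.data.frame(demes),
            all(c("label", "Ne", "n_samples") %in% names(demes)))
  demes$label <- as.character(demes$label)
  if (anyDuplicated(demes$label)) stop("deme labels must be unique")
  if (any(demes$Ne <= 0)) stop("all Ne must be > 0")
  if (any(demes$n_samples < 0)) stop("n_samples must be >= 0")
  if (!is.null(mu) && mu < 0) stop("mu must be >= 0")
  nd <- nrow(demes)
  if (is.null(migration0)) migration0 <- matrix(0, nd, nd)
  stopifnot(nrow(migration0) == nd, ncol(migration0) == nd)
  if (any(migration0 < 0)) stop("migration rates must be >= 0")
  diag(migration0) <- 0
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(time = numeric(), kind = character(),
                         source = character(), dest = character(),
                         value = numeric())
  }
  events$kind <- as.character(events$kind)
  if (!all(events$kind %in% names(.EVENT_KINDS)))
    stop("unknown event kind: ",
         paste(setdiff(events$kind, names(.EVENT_KINDS)), collapse = ", "))
  if (is.unsorted(events$time)) stop("event times must be non-decreasing")
  if (any(events$time < 0)) stop("event times must be >= 0")
  pulses <- events$kind == "admixture_pulse"
  if (any(pulses & (events$value < 0 | events$value > 1)))
    stop("admixture fractions must lie in [0, 1]")
  bad <- !(events$source %in% c(demes$label, NA)) & events$kind != "migration_change"
  if (any(bad)) stop("event source not a deme label: ",
                     paste(unique(events$source[bad]), collapse = ", "))
  for (m in mats) {
    stopifnot(nrow(m) == nd, ncol(m) == nd)
    if (any(m < 0)) stop("migration rates must be >= 0")
  }
  d <- structure(list(demes = demes, events = events, migration0 = migration0,
                      mats = mats, mu = mu, gen_time_years = gen_time_years),
                 class = "demography")
  if (check_ancestry) .check_single_ancestor(d)
  d
}

# Lineage-trace the event program: sampled demes (plus anything reachable by
# migration) must funnel into exactly one terminal deme via splits/full pulses.
.check_single_ancestor <- function(d) {
  labels <- d$demes$label
  live <- labels[d$demes$n_samples > 0]
  if (length(live) == 0) stop("no sampled demes")
  reach <- d$migration0 > 0
  for (m in d$mats) reach <- reach | (m > 0)
  repeat {
    add <- labels[colSums(reach[labels %in% live, , drop = FALSE]) > 0 |
                  rowSums(reach[, labels %in% live, drop = FALSE]) > 0]
    new <- union(live, add)
    if (length(new) == length(live)) break
    live <- new
  }
  ev <- d$events
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "split" || (ev$kind[i] == "admixture_pulse" && ev$value[i] >= 1)) {
      if (ev$source[i] %in% live) {
        live <- setdiff(live, ev$source[i])
        live <- union(live, ev$dest[i])
      }
    } else if (ev$kind[i] == "admixture_pulse" && ev$value[i] > 0) {
      if (ev$source[i] %in% live) live <- union(live, ev$dest[i])
    }
  }
  if (length(live) != 1)
    stop("event program does not leave exactly one ancestral deme (left: ",
         paste(live, collapse = ", "), ")")
  invisible(TRUE)
}

#' @export
print.demography <- function(x, ...) {
  cat("demography:", nrow(x$demes), "demes,", nrow(x$events), "events, mu =",
      x$mu, ",", x$gen_time_years, "y/gen\n")
  cat("  demes:", paste0(x$demes$label, " (Ne=", x$demes$Ne, ", n=",
                         x$demes$n_samples, ")", collapse = ", "), "\n")
  if (nrow(x$events))
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  t=%g %s %s -> %s (%g)\n", x$events$time[i],
                  x$events$kind[i], x$events$source[i], x$events$dest[i],
                  x$events$value[i]))
  invisible(x)
}

# Lower an R demography to the flat list the C++ engine consumes.
.demog_cpp <- function(d) {
  labels <- d$demes$label
  idx <- function(lab) {
    i <- match(lab, labels)
    ifelse(is.na(i), 0L, as.integer(i - 1L))
  }
  ev <- d$events
  n <- nrow(ev)
  list(Ne = as.numeric(d$demes$Ne),
       samples = as.integer(d$demes$n_samples),
       migration = d$migration0,
       events = data.frame(
         time = as.numeric(ev$time),
         kind = unname(.EVENT_KINDS[ev$kind]),
         src = if (n) idx(ev$source) else integer(),
         dst = if (n) idx(ev$dest) else integer(),
         value = as.numeric(ev$value),
         mat = if (n) ifelse(ev$kind == "migration_change",
                             as.integer(ev$value) - 1L, -1L) else integer()),
       mats = d$mats)
}

#' Convert between thousands of years (ka) and generations
#'
#' @param ka,gen time in ka / in generations.
#' @param gen_time_years years per generation (default 10).
#' @return time in the other unit.
#' @export
ka_to_gen <- function(ka, gen_time_years = 10) ka * 1000 / gen_time_years

#' @rdname ka_to_gen
#' @export
gen_to_ka <- function(gen, gen_time_years = 10) gen * gen_time_years / 1000

.POPS5 <- c("SW", "SE", "C", "NC", "N")
# geographically adjacent cluster pairs (stepping-stone neighbourhood)
.ADJ5 <- rbind(c("SW", "SE"), c("SW", "C"), c("SE", "C"),
               c("C", "NC"), c("C", "N"), c("NC", "N"))

.adj_matrix <- function(labels, pairs, m) {
  M <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_len(nrow(pairs))) {
    M[pairs[i, 1], pairs[i, 2]] <- m
    M[pairs[i, 2], pairs[i, 1]] <- m
  }
  M
}

.full_matrix <- function(labels, m) {
  M <- matrix(m, length(labels), length(labels))
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  M
}

.MODEL_NAMES <- c("origin_SW", "origin_C", "model1_stepping",
                  "model2_SE_admix", "model3_NC_admix", "model4_SE_NC_admix",
                  "model5_IM", "model6_independent",
                  "within_SW", "within_C", "within_NC", "within_N")

#' Parameter spaces for the named demographic models
#'
#' Bounds follow the fitting priors: diploid sizes uniform on [50, 1e4]
#' (log scale for searching), divergence times uniform on [100, 5e4]
#' generations, per-generation migration rates on [1e-6, 1e-2] (log scale),
#' admixture fractions on (0, 1).
#'
#' @param name a model name (see \code{\link{build_named_model}}).
#' @return data.frame with columns \code{param}, \code{lower}, \code{upper},
#'   \code{scale}.
#' @export
param_space <- function(name) {
  name <- match.arg(name, .MODEL_NAMES)
  row <- function(p, lo, hi, sc) data.frame(param = p, lower = lo, upper = hi,
                                            scale = sc)
  ne <- function(p) row(p, 50, 1e4, "log")
  tt <- function(p) row(p, 100, 5e4, "linear")
  # within-cluster divergences are recent (decades-scale); wider lower bound
  tw <- function(p) row(p, 5, 5e4, "linear")
  mm <- function(p) row(p, 1e-6, 1e-2, "log")
  aa <- function(p) row(p, 0, 1, "linear")
  sp <- switch(name,
    origin_SW = ,
    origin_C = ,
    model1_stepping = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                            tt(c("T_SWC", "T_CN", "T_NC", "T_SE")), mm("m")),
    model2_SE_admix = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                            tt(c("T_SWC", "T_CN", "T_NC", "T_SE")),
                            aa("a_SE"), mm("m")),
    model3_NC_admix = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                            tt(c("T_SWC", "T_CN", "T_NC", "T_SE")),
                            aa("a_NC"), mm("m")),
    model4_SE_NC_admix = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                               tt(c("T_SWC", "T_CN", "T_NC", "T_SE")),
                               aa(c("a_SE", "a_NC")), mm("m")),
    model5_IM = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                      tt("T_SWC"), mm("m")),
    model6_independent = rbind(ne(c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC")),
                               tt(c("T_SWC", "T_CN", "T_NC", "T_SE")), mm("m")),
    within_SW = ,
    within_NC = rbind(ne(c("N_1", "N_2", "N_3", "N_ANC")), tw(c("T_1", "T_2")),
                      mm("m")),
    within_C = ,
    within_N = rbind(ne(c("N_1", "N_2", "N_ANC")), tw("T_1"), mm("m")))
  rownames(sp) <- NULL
  sp
}

#' Synthetic-truth default parameters for the named models
#'
#' For the five-cluster admixture model these are the study conditions used
#' throughout the synthetic analyses: divergence/admixture times at the
#' reported best-fit values (SW-C split 128.5 ka, C-N split 106.3 ka,
#' NC admixture 13.5 ka, SE admixture 8.2 ka, at 10 years/generation) and
#' admixture fractions 0.37 (SE from SW) and 0.81 (NC from N). Effective
#' sizes and the shared migration rate are mid-prior values (see the methods
#' vignette) chosen so split depths are of order one coalescent unit.
#'
#' @param name model name.
#' @return named numeric vector of parameter values.
#' @export
default_params <- function(name) {
  name <- match.arg(name, .MODEL_NAMES)
  base5 <- c(N_SW = 5000, N_SE = 1000, N_C = 8000, N_NC = 1000, N_N = 3000,
             N_ANC = 5000, T_SWC = 12850, T_CN = 10630, T_NC = 1350,
             T_SE = 820, m = 1e-4)
  switch(name,
    origin_SW = ,
    origin_C = ,
    model1_stepping = ,
    model6_independent = base5,
    model2_SE_admix = c(base5, a_SE = 0.37),
    model3_NC_admix = c(base5, a_NC = 0.81),
    model4_SE_NC_admix = c(base5, a_SE = 0.37, a_NC = 0.81),
    model5_IM = base5[c("N_SW", "N_SE", "N_C", "N_NC", "N_N", "N_ANC",
                        "T_SWC", "m")],
    within_SW = ,
    within_NC = c(N_1 = 300, N_2 = 150, N_3 = 100, N_ANC = 300, T_1 = 61,
                  T_2 = 30, m = 1e-3),
    within_C = ,
    within_N = c(N_1 = 300, N_2 = 150, N_ANC = 300, T_1 = 40, m = 1e-3))
}

.check_params <- function(name, params) {
  sp <- param_space(name)
  missing <- setdiff(sp$param, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", name, ": ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(sp))) {
    v <- params[[sp$param[i]]]
    if (v < sp$lower[i] || v > sp$upper[i])
      stop("parameter ", sp$param[i], " = ", v, " outside bounds [",
           sp$lower[i], ", ", sp$upper[i], "] for ", name)
  }
  invisible(TRUE)
}

.ev <- function(time, kind, source, dest = NA_character_, value = 0) {
  data.frame(time = time, kind = kind, source = source, dest = dest,
             value = value)
}

#' Build one of the named demographic models
#'
#' Encodes the competing origin/dispersal hypotheses for the five genetic
#' clusters (SW, SE, C, NC, N) plus the four within-cluster divergence models.
#' Between-cluster scenarios: two serial-founder origin models
#' (\code{origin_SW}, \code{origin_C}); a stepping-stone split model
#' (\code{model1_stepping}); stepping-stone with an admixed origin of SE
#' (\code{model2_SE_admix}), of NC (\code{model3_NC_admix}), or of both
#' (\code{model4_SE_NC_admix}, the best-fitting scenario); a star
#' isolation-with-migration model (\code{model5_IM}); and the stepping-stone
#' topology with unrestricted pairwise migration (\code{model6_independent}).
#' An admixed deme is encoded as a pulse of fraction \code{a} into its minor
#' parent immediately followed by a split of the remainder into its major
#' parent at the same time, so a fraction of 1 is event-for-event identical to
#' a plain split. For \code{model4_SE_NC_admix} the ordering
#' \code{T_SE < T_NC < T_CN < T_SWC} (backward time) is enforced.
#'
#' @param name one of \code{origin_SW}, \code{origin_C},
#'   \code{model1_stepping}, \code{model2_SE_admix}, \code{model3_NC_admix},
#'   \code{model4_SE_NC_admix}, \code{model5_IM}, \code{model6_independent},
#'   \code{within_SW}, \code{within_C}, \code{within_NC}, \code{within_N}.
#' @param params named vector/list of parameter values (see
#'   \code{\link{param_space}}); defaults to \code{\link{default_params}}.
#' @param n_samples haploid sample sizes, recycled over demes (default 10
#'   haploids, i.e. 5 diploids, per deme).
#' @param mu,gen_time_years mutation rate and generation time.
#' @return a \code{\link{demography}}.
#' @export
build_named_model <- function(name, params = default_params(name),
                              n_samples = 10, mu = 1.36e-8,
                              gen_time_years = 10) {
  if (!name %in% .MODEL_NAMES)
    stop("unknown model name: ", name, " (known: ",
         paste(.MODEL_NAMES, collapse = ", "), ")")
  params <- as.list(params)
  .check_params(name, params)
  p <- params
  ord <- function(constraint, ok) {
    if (!ok) stop("event-time ordering violated for ", name, ": requires ",
                  constraint)
  }
  if (name %in% c("origin_SW", "origin_C", "model1_stepping",
                  "model2_SE_admix", "model3_NC_admix", "model4_SE_NC_admix",
                  "model5_IM", "model6_independent")) {
    labels <- .POPS5
    Ne <- c(p$N_SW, p$N_SE, p$N_C, p$N_NC, p$N_N)
    demes <- data.frame(label = labels, Ne = Ne,
                        n_samples = rep_len(n_samples, 5))
    mig <- if (name %in% c("model5_IM", "model6_independent"))
      .full_matrix(labels, p$m) else .adj_matrix(labels, .ADJ5, p$m)
    admix_origin <- function(t, child, minor, major, frac)
      rbind(.ev(t, "admixture_pulse", child, minor, frac),
            .ev(t, "split", child, major))
    ev <- switch(name,
      origin_SW = {
        ord("T_SE < T_NC < T_CN < T_SWC",
            p$T_SE < p$T_NC && p$T_NC < p$T_CN && p$T_CN < p$T_SWC)
        rbind(.ev(p$T_SE, "split", "SE", "SW"),
              .ev(p$T_NC, "split", "N", "NC"),
              .ev(p$T_CN, "split", "NC", "C"),
              .ev(p$T_SWC, "split", "C", "SW"),
              .ev(p$T_SWC, "size_change", "SW", value = p$N_ANC))
      },
      origin_C = {
        ord("T_SE < T_NC < T_CN < T_SWC",
            p$T_SE < p$T_NC && p$T_NC < p$T_CN && p$T_CN < p$T_SWC)
        rbind(.ev(p$T_SE, "split", "SE", "SW"),
              .ev(p$T_NC, "split", "NC", "N"),
              .ev(p$T_CN, "split", "SW", "C"),
              .ev(p$T_SWC, "split", "N", "C"),
              .ev(p$T_SWC, "size_change", "C", value = p$N_ANC))
      },
      model5_IM = {
        rbind(.ev(p$T_SWC, "split", "SE", "SW"),
              .ev(p$T_SWC, "split", "NC", "SW"),
              .ev(p$T_SWC, "split", "N", "SW"),
              .ev(p$T_SWC, "split", "C", "SW"),
              .ev(p$T_SWC, "size_change", "SW", value = p$N_ANC))
      },
      {
        # stepping-stone family: SE and NC are the youngest demes, formed
        # either by split or by admixture from their two neighbours
        ord("T_SE < T_NC < T_CN < T_SWC",
            p$T_SE < p$T_NC && p$T_NC < p$T_CN && p$T_CN < p$T_SWC)
        a_SE <- if (name %in% c("model2_SE_admix", "model4_SE_NC_admix"))
          p$a_SE else 1.0
        a_NC <- if (name %in% c("model3_NC_admix", "model4_SE_NC_admix"))
          p$a_NC else 1.0
        rbind(admix_origin(p$T_SE, "SE", "SW", "C", a_SE),
              admix_origin(p$T_NC, "NC", "N", "C", a_NC),
              .ev(p$T_CN, "split", "N", "C"),
              .ev(p$T_SWC, "split", "C", "SW"),
              .ev(p$T_SWC, "size_change", "SW", value = p$N_ANC))
      })
    return(demography(demes, ev, migration0 = mig, mu = mu,
                      gen_time_years = gen_time_years))
  }
  # within-cluster divergence models: 2- or 3-deme isolation-with-migration
  k <- if (name %in% c("within_SW", "within_NC")) 3L else 2L
  cl <- sub("within_", "", name)
  labels <- paste0(cl, seq_len(k))
  Ne <- unlist(p[paste0("N_", seq_len(k))])
  demes <- data.frame(label = labels, Ne = Ne,
                      n_samples = rep_len(n_samples, k))
  if (k == 3L) {
    ord("T_2 < T_1", p$T_2 < p$T_1)
    ev <- rbind(.ev(p$T_2, "split", labels[3], labels[2]),
                .ev(p$T_1, "split", labels[2], labels[1]),
                .ev(p$T_1, "size_change", labels[1], value = p$N_ANC))
  } else {
    ev <- rbind(.ev(p$T_1, "split", labels[2], labels[1]),
                .ev(p$T_1, "size_change", labels[1], value = p$N_ANC))
  }
  demography(demes, ev, migration0 = .full_matrix(labels, p$m), mu = mu,
             gen_time_years = gen_time_years)
}

#' Write / read a model definition file
#'
#' Key-value (YAML) description of a named model: the model name, fixed
#' parameter values, and free parameters with bounds. Round-trips losslessly.
#'
#' @param x list with elements \code{model}, \code{fixed} (named list) and
#'   \code{free} (named list of \code{c(lower, upper)}).
#' @param path file path.
#' @return \code{read_model_spec} returns the list; \code{write_model_spec}
#'   returns \code{path} invisibly.
#' @export
write_model_spec <- function(x, path) {
  stopifnot(is.list(x), !is.null(x$model))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$model)) stop("model spec missing 'model' key")
  x$fixed <- lapply(x$fixed, as.numeric)
  x$free <- lapply(x$free, as.numeric)
  x
}
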