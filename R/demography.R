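#' Parameterized demographic model
#'
#' A rooted population tree with one constant diploid effective size per
#' branch, dated splits, dated pulse admixtures (an instantaneous transfer
#' of a fraction `alpha` of the destination's ancestry from a source
#' lineage), dated sampling, a per-generation mutation rate and a
#' generation time converting years to generations. Times are stored in
#' years ago; all coalescent computation rescales them to generations via
#' the generation time.
#'
#' @param populations `data.frame` with columns `name`, `ne` (diploid).
#' @param splits `data.frame` with columns `time_ya`, `child`, `parent`:
#'   backward in time, `child` merges into `parent` at `time_ya`.
#' @param pulses `data.frame` with columns `time_ya`, `source`, `dest`,
#'   `alpha`: forward in time, a fraction `alpha` of `dest` ancestry
#'   arrives from `source` at `time_ya`.
#' @param samples `data.frame` with columns `population`, `n_haploids`,
#'   `time_ya`.
#' @param mutation_rate per site per generation.
#' @param generation_time years per generation.
#' @param assumed character vector of parameter paths whose values are
#'   assumptions rather than estimates (bookkeeping only).
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(populations, splits = NULL, pulses = NULL,
                             samples = NULL, mutation_rate = 1.25e-8,
                             generation_time = 29, assumed = character()) {
  empty <- function(...) {
    cols <- list(...)
    structure(cols, class = "data.frame", row.names = integer(0),
              names = names(cols))
  }
  splits <- splits %||% empty(time_ya = numeric(), child = character(),
                              parent = character())
  pulses <- pulses %||% empty(time_ya = numeric(), source = character(),
                              dest = character(), alpha = numeric())
  samples <- samples %||% empty(population = character(),
                                n_haploids = integer(), time_ya = numeric())
  m <- structure(list(populations = populations, splits = splits,
                      pulses = pulses, samples = samples,
                      mutation_rate = mutation_rate,
                      generation_time = generation_time,
                      assumed = assumed),
                 class = "demography_model")
  validate_demography(m)
  m
}

validate_demography <- function(m) {
  pops <- m$populations$name
  if (anyDuplicated(pops)) stop("duplicate population names")
  if (any(m$populations$ne <= 0)) stop("effective sizes must be positive")
  if (m$generation_time <= 0) stop("generation time must be positive")
  all_named <- c(m$splits$child, m$splits$parent, m$pulses$source,
                 m$pulses$dest, m$samples$population)
  unknown <- setdiff(all_named, pops)
  if (length(unknown))
    stop("undeclared population(s): ", paste(unique(unknown), collapse = ", "))
  if (anyDuplicated(m$splits$child))
    stop("a population can split from its parent only once")
  # reachability: following child -> parent must reach a single root
  parent_of <- stats::setNames(m$splits$parent, m$splits$child)
  roots <- setdiff(pops, names(parent_of))
  if (length(pops) > 1 && length(roots) != 1)
    stop("split graph must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  for (p in pops) {
    seen <- character()
    q <- p
    while (q %in% names(parent_of)) {
      if (q %in% seen) stop("cyclic split graph at population ", p)
      seen <- c(seen, q)
      q <- parent_of[[q]]
    }
  }
  # a child's split must predate (be more recent than) its parent's own split
  origin <- origin_times(m)
  for (i in seq_len(nrow(m$splits))) {
    ch <- m$splits$child[i]
    if (m$splits$time_ya[i] >= origin[m$splits$parent[i]])
      stop("split of ", ch, " is older than its parent's own origin")
  }
  if (nrow(m$pulses)) {
    if (any(m$pulses$alpha < 0 | m$pulses$alpha > 1))
      stop("pulse fraction alpha must lie in [0, 1]: pulse ",
           which(m$pulses$alpha < 0 | m$pulses$alpha > 1)[1])
    for (i in seq_len(nrow(m$pulses))) {
      t <- m$pulses$time_ya[i]
      if (t >= origin[m$pulses$source[i]] || t >= origin[m$pulses$dest[i]])
        stop("pulse ", i, " (", m$pulses$source[i], " -> ", m$pulses$dest[i],
             ") predates the origin of an involved population")
    }
  }
  for (i in seq_len(nrow(m$samples))) {
    sp <- m$samples$population[i]
    if (m$samples$time_ya[i] >= origin[sp])
      stop("sample of ", sp, " is older than the population's origin")
  }
  invisible(m)
}

# Time (years ago) each population originates; the root is Inf.
origin_times <- function(m) {
  origin <- stats::setNames(rep(Inf, nrow(m$populations)),
                            m$populations$name)
  origin[m$splits$child] <- m$splits$time_ya
  origin
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model> %d populations, %d splits, %d pulses, %d sample specs\n",
              nrow(x$populations), nrow(x$splits), nrow(x$pulses),
              nrow(x$samples)))
  cat(sprintf("  mu = %g /site/gen, generation time = %g y\n",
              x$mutation_rate, x$generation_time))
  if (nrow(x$splits)) {
    ord <- order(x$splits$time_ya)
    for (i in ord)
      cat(sprintf("  split %8.0f ya: %s <- %s\n", x$splits$time_ya[i],
                  x$splits$parent[i], x$splits$child[i]))
  }
  for (i in seq_len(nrow(x$pulses)))
    cat(sprintf("  pulse %8.0f ya: %s -> %s (alpha = %.3f)\n",
                x$pulses$time_ya[i], x$pulses$source[i], x$pulses$dest[i],
                x$pulses$alpha[i]))
  invisible(x)
}

#' Load a demographic model from a YAML config
#'
#' @param path file path, or a YAML string.
#' @return A [demography_model()].
#' @export
load_model <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  pops <- do.call(rbind, lapply(cfg$populations, function(p)
    data.frame(name = p$name, ne = as.numeric(p$ne))))
  tolist <- function(entries, cols) {
    if (is.null(entries) || !length(entries)) return(NULL)
    do.call(rbind, lapply(entries, function(e) {
      as.data.frame(e[cols], stringsAsFactors = FALSE)
    }))
  }
  assumed <- character()
  mark <- function(entries, path_fun) {
    for (e in entries) if (isTRUE(e$assumed))
      assumed <<- c(assumed, path_fun(e))
    invisible(NULL)
  }
  mark(cfg$populations, function(e) paste0("ne.", e$name))
  mark(cfg$splits, function(e) paste0("split.", e$child))
  mark(cfg$pulses, function(e) paste0("pulse.", e$source, ".", e$dest, ".time"))
  mark(cfg$samples, function(e) paste0("sample.", e$population, ".time"))
  demography_model(
    populations = pops,
    splits = tolist(cfg$splits, c("time_ya", "child", "parent")),
    pulses = tolist(cfg$pulses, c("time_ya", "source", "dest", "alpha")),
    samples = tolist(cfg$samples, c("population", "n_haploids", "time_ya")),
    mutation_rate = cfg$mutation_rate %||% 1.25e-8,
    generation_time = cfg$generation_time %||% 29,
    assumed = assumed)
}

#' Write a demographic model to a YAML config
#'
#' @param model a [demography_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rowlist <- function(df) lapply(seq_len(nrow(df)), function(i)
    as.list(df[i, , drop = FALSE]))
  cfg <- list(generation_time = model$generation_time,
              mutation_rate = model$mutation_rate,
              populations = lapply(seq_len(nrow(model$populations)),
                                   function(i) list(
                                     name = model$populations$name[i],
                                     ne = model$populations$ne[i])),
              splits = rowlist(model$splits),
              pulses = rowlist(model$pulses),
              samples = rowlist(model$samples))
  for (i in seq_along(cfg$populations))
    if (paste0("ne.", cfg$populations[[i]]$name) %in% model$assumed)
      cfg$populations[[i]]$assumed <- TRUE
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Resolve a parameter path to a (getter, setter) pair. Paths:
#   ne.<pop>; split.<child>; pulse.<source>.<dest>.alpha;
#   pulse.<source>.<dest>.time; sample.<pop>.time; sample.<pop>.n;
#   mu; generation_time
resolve_param <- function(model, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  fail <- function() stop("unknown parameter path '", path, "'; valid paths: ",
                          paste(list_parameters(model), collapse = ", "))
  if (parts[1] == "mu") {
    list(get = function(m) m$mutation_rate,
         set = function(m, v) { m$mutation_rate <- v; m })
  } else if (parts[1] == "generation_time") {
    list(get = function(m) m$generation_time,
         set = function(m, v) { m$generation_time <- v; m })
  } else if (parts[1] == "ne" && length(parts) == 2) {
    i <- match(parts[2], model$populations$name)
    if (is.na(i)) fail()
    list(get = function(m) m$populations$ne[i],
         set = function(m, v) { m$populations$ne[i] <- v; m })
  } else if (parts[1] == "split" && length(parts) == 2) {
    i <- match(parts[2], model$splits$child)
    if (is.na(i)) fail()
    list(get = function(m) m$splits$time_ya[i],
         set = function(m, v) { m$splits$time_ya[i] <- v; m })
  } else if (parts[1] == "pulse" && length(parts) == 4) {
    i <- which(model$pulses$source == parts[2] &
               model$pulses$dest == parts[3])
    if (!length(i) || !parts[4] %in% c("alpha", "time")) fail()
    i <- i[1]
    col <- if (parts[4] == "alpha") "alpha" else "time_ya"
    list(get = function(m) m$pulses[[col]][i],
         set = function(m, v) { m$pulses[[col]][i] <- v; m })
  } else if (parts[1] == "sample" && length(parts) == 3) {
    i <- match(parts[2], model$samples$population)
    if (is.na(i) || !parts[3] %in% c("time", "n")) fail()
    col <- if (parts[3] == "time") "time_ya" else "n_haploids"
    list(get = function(m) m$samples[[col]][i],
         set = function(m, v) { m$samples[[col]][i] <- v; m })
  } else fail()
}

#' List, read and set model parameters by path
#'
#' Parameter paths name every tunable quantity: `ne.<pop>`,
#' `split.<child>` (time, years ago), `pulse.<source>.<dest>.alpha`,
#' `pulse.<source>.<dest>.time`, `sample.<pop>.time`, `sample.<pop>.n`,
#' `mu`, `generation_time`.
#'
#' @param model a [demography_model()].
#' @param path parameter path string.
#' @param value new value.
#' @return `set_parameter` returns a new validated model (the input is
#'   unchanged); `get_parameter` the current value; `list_parameters` all
#'   valid paths.
#' @export
set_parameter <- function(model, path, value) {
  m <- resolve_param(model, path)$set(model, value)
  validate_demography(m)
  m
}

#' @rdname set_parameter
#' @export
get_parameter <- function(model, path) resolve_param(model, path)$get(model)

#' @rdname set_parameter
#' @export
list_parameters <- function(model) {
  c("mu", "generation_time",
    paste0("ne.", model$populations$name),
    if (nrow(model$splits)) paste0("split.", model$splits$child),
    if (nrow(model$pulses))
      c(paste0("pulse.", model$pulses$source, ".", model$pulses$dest, ".alpha"),
        paste0("pulse.", model$pulses$source, ".", model$pulses$dest, ".time")),
    if (nrow(model$samples))
      c(paste0("sample.", model$samples$population, ".time"),
        paste0("sample.", model$samples$population, ".n")))
}

#' The packaged final demographic model of the Kola Bronze Age cohort
#'
#' Six-branch model: Yoruba (YRI) as the African root branch, Loschbour
#' carrying the Western Eurasian lineage, CHB the Eastern Eurasian lineage,
#' EEHG (Eastern European hunter-gatherers), the Eastern Siberia LNBA
#' lineage, and BOO (Bolshoy Oleni Ostrov). Fitted values: YRI-Eurasian
#' split 87,790 ya; West-East Eurasian split 53,010 ya; Eastern Siberia
#' LNBA-CHB divergence 21,580 ya; pulses CHB->EEHG 9.4%, EEHG->Eastern
#' Siberia LNBA 12.5%, Eastern Siberia LNBA->BOO 39.8% at 4,086 ya; Ne
#' 1690 (Eastern Siberia LNBA), 2470 (EEHG), 235 (BOO). Quantities not
#' estimated (outgroup/ancestral Ne, sampling ages, ancient pulse times,
#' the EEHG and BOO branch origins) are marked `assumed` in the config and
#' freely overridable.
#'
#' @return A [demography_model()].
#' @export
boo_final_model <- function() {
  load_model(system.file("extdata", "boo_final_model.yaml",
                         package = "adnapop", mustWork = TRUE))
}
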