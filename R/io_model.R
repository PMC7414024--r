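# The native model file: a deterministic YAML serialization whose
# serialize -> load -> serialize round trip is byte-identical (numbers are
# emitted with 17 significant digits, which survive parse/re-format).

num <- function(x) {
  ifelse(is.na(x), "~",
         ifelse(x == floor(x) & abs(x) < 1e15,
                sprintf("%.0f.0", x), sprintf("%.17g", x)))
}

chr <- function(x) ifelse(is.na(x), "~", x)

#' Serialize a model to the native text format
#'
#' @param model a `pi_model`.
#' @return a single character string (YAML).
#' @export
model_to_yaml <- function(model) {
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add("picycle_model: 1")
  add("metadata:")
  md <- model$metadata
  if (!length(md)) add("  {}")
  for (k in names(md)) add("  ", k, ": ", as.character(md[[k]]))
  add("compartments:")
  for (i in seq_len(nrow(model$compartments)))
    add("  - {name: ", model$compartments$name[i],
        ", volume: ", num(model$compartments$volume[i]), "}")
  add("species:")
  for (i in seq_len(nrow(model$species)))
    add("  - {name: ", model$species$name[i],
        ", compartment: ", model$species$compartment[i],
        ", initial: ", num(model$species$initial[i]),
        ", role: ", model$species$role[i], "}")
  add("rates:")
  for (i in seq_len(nrow(model$rates)))
    add("  - {id: ", model$rates$id[i],
        ", basal: ", num(model$rates$basal[i]),
        ", activated: ", num(model$rates$activated[i]), "}")
  add("reactions:")
  for (r in model$reactions) {
    add("  - id: ", r$id)
    add("    reactants: {",
        paste0(names(r$reactants), ": ", num(r$reactants), collapse = ", "),
        "}")
    add("    products: {",
        paste0(names(r$products), ": ", num(r$products), collapse = ", "),
        "}")
    add("    rate: ", r$rate)
    add("    enzyme: ", chr(r$enzyme))
  }
  add("binding:")
  if (!nrow(model$binding_pairs)) add("  []")
  for (i in seq_len(nrow(model$binding_pairs))) {
    b <- model$binding_pairs[i, ]
    add("  - {lipid: ", b$lipid, ", bp: ", b$bp, ", complex: ", b$complex,
        ", kon: ", b$kon, ", koff: ", b$koff,
        ", bp_total: ", num(b$bp_total), "}")
  }
  add("activation:")
  a <- model$activation
  if (is.null(a)) add("  ~") else {
    add("  t_activation: ", num(a$t_activation))
    add("  receptor_count: ", num(a$receptor_count))
    add("  rate_switches: [", paste(a$rate_switches, collapse = ", "), "]")
    add("  termination: ", a$termination)
    add("  termination_timescale: ", num(a$termination_timescale))
  }
  paste0(paste(L, collapse = "\n"), "\n")
}

#' Write a model file
#' @param model a `pi_model`.
#' @param path destination path.
#' @export
write_model_file <- function(model, path) {
  writeLines(model_to_yaml(model), path, sep = "")
  invisible(path)
}

#' Read a model file
#' @param path a file written by [write_model_file()].
#' @return a `pi_model`.
#' @export
read_model_file <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y) || is.null(y$picycle_model))
    stop("not a picycle model file: ", path)
  comp <- do.call(rbind, lapply(y$compartments, function(x)
    data.frame(name = x$name, volume = as.numeric(x$volume),
               stringsAsFactors = FALSE)))
  species <- do.call(rbind, lapply(y$species, function(x)
    data.frame(name = x$name, compartment = x$compartment,
               initial = as.numeric(x$initial), role = x$role,
               stringsAsFactors = FALSE)))
  rates <- do.call(rbind, lapply(y$rates, function(x)
    data.frame(id = x$id, basal = as.numeric(x$basal),
               activated = if (is.null(x$activated)) NA_real_ else
                 as.numeric(x$activated), stringsAsFactors = FALSE)))
  reactions <- lapply(y$reactions, function(x)
    list(id = x$id, reactants = unlist(x$reactants),
         products = unlist(x$products), rate = x$rate,
         enzyme = if (is.null(x$enzyme)) NA_character_ else x$enzyme))
  binding <- if (!length(y$binding)) empty_binding_pairs() else
    do.call(rbind, lapply(y$binding, function(x)
      data.frame(lipid = x$lipid, bp = x$bp, complex = x$complex,
                 kon = x$kon, koff = x$koff,
                 bp_total = as.numeric(x$bp_total), stringsAsFactors = FALSE)))
  act <- if (is.null(y$activation)) NULL else
    activation_scheme(t_activation = y$activation$t_activation,
                      receptor_count = y$activation$receptor_count,
                      rate_switches = unlist(y$activation$rate_switches),
                      termination = y$activation$termination,
                      termination_timescale = y$activation$termination_timescale)
  pi_model(compartments = comp, species = species, reactions = reactions,
           rates = rates, binding_pairs = binding, activation = act,
           metadata = y$metadata)
}

# Semantic equality of two models (order-insensitive), for round-trip checks.
model_semantically_equal <- function(a, b, tol = 1e-12) {
  srt <- function(d, k) d[order(d[[k]]), , drop = FALSE]
  eqdf <- function(x, y, k) {
    x <- srt(x, k); y <- srt(y, k)
    isTRUE(all.equal(x, y, tolerance = tol, check.attributes = FALSE))
  }
  if (!eqdf(a$compartments, b$compartments, "name")) return(FALSE)
  if (!eqdf(a$species, b$species, "name")) return(FALSE)
  if (!eqdf(a$rates, b$rates, "id")) return(FALSE)
  if (nrow(a$binding_pairs) != nrow(b$binding_pairs)) return(FALSE)
  if (nrow(a$binding_pairs) &&
      !eqdf(a$binding_pairs, b$binding_pairs, "lipid")) return(FALSE)
  ids <- vapply(a$reactions, `[[`, "", "id")
  ids_b <- vapply(b$reactions, `[[`, "", "id")
  if (!setequal(ids, ids_b)) return(FALSE)
  for (id in ids) {
    ra <- a$reactions[[which(ids == id)]]
    rb <- b$reactions[[which(ids_b == id)]]
    if (!identical(sort(names(ra$reactants)), sort(names(rb$reactants))) ||
        !identical(sort(names(ra$products)), sort(names(rb$products))) ||
        !isTRUE(all.equal(ra$reactants[sort(names(ra$reactants))],
                          rb$reactants[sort(names(rb$reactants))])) ||
        !identical(ra$rate, rb$rate) || !identical(ra$enzyme, rb$enzyme))
      return(FALSE)
  }
  if (is.null(a$activation) != is.null(b$activation)) return(FALSE)
  if (!is.null(a$activation) &&
      !isTRUE(all.equal(unclass(a$activation), unclass(b$activation),
                        tolerance = tol))) return(FALSE)
  TRUE
}
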