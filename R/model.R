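#' Construct a Golgi model
#'
#' An ordered stack of cisternae (index 1 = cis), a residence time per
#' cisterna, a per-enzyme per-cisterna effective-rate matrix and the
#' distribution of glycan species entering from the ER.  "Effective rate"
#' is the composite of enzyme level, nucleotide-sugar availability and
#' intrinsic catalytic rate; only relative values matter.
#'
#' @param rates numeric matrix, rows = enzymes (rownames required),
#'   columns = cisternae, entries in min^-1, all >= 0.
#' @param residence_time minutes per cisterna; scalar (recycled) or one
#'   value per cisterna.  Default 10 minutes.
#' @param input_distribution named fractions summing to 1 over ER-exit
#'   species.  Names are pathway species (`"Man8"`, `"Man9"`, `"Man9Glc"`)
#'   or explicit notation strings.  Default 80% Man8, 15% Man9, 5% Man9Glc.
#' @return An object of class `"golgi_model"`.
#' @export
golgi_model <- function(rates,
                        residence_time = 10,
                        input_distribution = c(Man8 = 0.80, Man9 = 0.15,
                                               Man9Glc = 0.05)) {
  rates <- as.matrix(rates)
  if (is.null(rownames(rates))) stop("rates must have enzyme rownames")
  if (ncol(rates) < 1L) stop("at least one cisterna is required")
  if (any(rates < 0)) stop("rates must be >= 0")
  residence_time <- rep_len(as.numeric(residence_time), ncol(rates))
  if (any(residence_time <= 0)) stop("residence_time must be > 0")
  if (is.null(names(input_distribution)) || any(input_distribution < 0))
    stop("input_distribution must be named and non-negative")
  if (abs(sum(input_distribution) - 1) > 1e-9)
    stop("input_distribution must sum to 1")
  colnames(rates) <- paste0("c", seq_len(ncol(rates)))
  structure(list(rates = rates, residence_time = residence_time,
                 input_distribution = input_distribution),
            class = "golgi_model")
}

#' @export
print.golgi_model <- function(x, ...) {
  cat("<golgi_model> ", nrow(x$rates), " enzymes x ", ncol(x$rates),
      " cisternae; residence ", paste(x$residence_time, collapse = "/"),
      " min\n", sep = "")
  cat("  input:", paste0(names(x$input_distribution), "=",
                         signif(x$input_distribution, 3), collapse = ", "), "\n")
  print(signif(x$rates, 3))
  invisible(x)
}

n_cisternae <- function(model) ncol(model$rates)

#' Scale the rates of selected enzymes
#'
#' Multiplies an enzyme's effective rate in every cisterna by a factor
#' (0 = knockout-like, <1 = knockdown-like).
#'
#' @param model a [golgi_model()].
#' @param multipliers named numeric vector, names = enzymes.
#' @return The modified [golgi_model()].
#' @export
scale_enzymes <- function(model, multipliers) {
  unknown <- setdiff(names(multipliers), rownames(model$rates))
  if (length(unknown))
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  for (e in names(multipliers))
    model$rates[e, ] <- model$rates[e, ] * multipliers[[e]]
  model
}

# Flatten / restore the rate matrix as a named parameter vector "ENZ.c1".
rates_to_params <- function(rates) {
  p <- as.numeric(rates)
  names(p) <- as.vector(outer(rownames(rates), colnames(rates),
                              function(e, c) paste0(e, ".", c)))
  p
}

params_to_rates <- function(params, template) {
  m <- template
  m[] <- params[as.vector(outer(rownames(m), colnames(m),
                                function(e, c) paste0(e, ".", c)))]
  m
}
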