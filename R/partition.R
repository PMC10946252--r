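## Rodgers-Rowland tissue-to-plasma partition coefficients.
##
## Tissue composition (fractional extracellular/intracellular water, neutral
## lipid, neutral phospholipid, and acidic phospholipid in mg/g tissue) from
## the Rodgers, Leahy & Rowland compilation used throughout mechanistic PBPK.
## pH: plasma 7.4, intracellular water 7.0, blood cells 7.22.

.tissue_composition <- data.frame(
  organ = c("adipose", "gut", "heart", "kidney", "liver", "lung",
            "muscle", "skin", "spleen", "bone", "brain", "rest"),
  f_ew  = c(0.135, 0.282, 0.320, 0.273, 0.161, 0.336,
            0.118, 0.382, 0.207, 0.100, 0.162, 0.320),
  f_iw  = c(0.017, 0.475, 0.456, 0.483, 0.573, 0.446,
            0.630, 0.291, 0.579, 0.346, 0.620, 0.456),
  f_nl  = c(0.853, 0.0487, 0.0115, 0.0207, 0.0348, 0.0030,
            0.0238, 0.0284, 0.0201, 0.0174, 0.0391, 0.0115),
  f_np  = c(0.0016, 0.0163, 0.0166, 0.0162, 0.0252, 0.0090,
            0.0072, 0.0111, 0.0198, 0.0016, 0.0015, 0.0166),
  ap    = c(0.40, 2.41, 2.25, 5.03, 4.56, 3.91,
            1.53, 1.32, 3.18, 0.67, 0.40, 2.25),
  stringsAsFactors = FALSE
)
## "rest" (lumped viscera/carcass) uses heart-like composition.

.bc_composition <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029, ap = 0.5)
.ph_plasma <- 7.4
.ph_iw <- 7.0
.ph_bc <- 7.22

## ionization factor 1 + 10^(pKa1-pH) + 10^(pKa1+pKa2-2pH) for (di)protic bases
.base_ionization <- function(pka, ph) {
  y <- 1
  if (length(pka) >= 1) y <- y + 10^(pka[1] - ph)
  if (length(pka) >= 2) y <- y + 10^(pka[1] + pka[2] - 2 * ph)
  y
}

## vegetable-oil:water partition coefficient from octanol logP
.p_vegoil <- function(logp) 10^(1.115 * logp - 1.35)

## acidic-phospholipid association constant derived from blood-cell
## partitioning of the unbound drug (moderate-to-strong bases)
.ka_ap <- function(compound, hct = 0.47) {
  kbc <- kpu_bc(hct, compound$rbp, compound$fup)
  yp <- .base_ionization(compound$pka_base, .ph_plasma)
  ybc <- .base_ionization(compound$pka_base, .ph_bc)
  pvo <- .p_vegoil(compound$logp)
  neutral <- (pvo * .bc_composition$f_nl +
                (0.3 * pvo + 0.7) * .bc_composition$f_np) / yp
  xbc <- 10^(compound$pka_base[1] - .ph_bc)
  num <- kbc - (ybc / yp) * .bc_composition$f_iw - neutral
  ka <- num * yp / ((.bc_composition$ap / 1000) * xbc)
  max(ka, 0)
}

#' Rodgers-Rowland tissue-to-plasma partition coefficient
#'
#' Mechanistic partition prediction for a moderate-to-strong base (strongest
#' basic pKa >= 7): partitioning into tissue water with intracellular pH
#' trapping, electrostatic association of the cation with acidic
#' phospholipids (association constant derived from blood-cell partitioning
#' of the unbound drug), and partitioning of the neutral species into neutral
#' lipid and phospholipid. For compounds without a basic pKa >= 7 the acidic
#' phospholipid term is dropped (neutral/weak-base form). The returned value
#' is \eqn{K_p = K_{pu} \times f_{up}}, before any global scale factor.
#'
#' @param compound a \code{compound_parameters} object.
#' @param organ one of the embedded tissue-composition records:
#'   adipose, gut, heart, kidney, liver, lung, muscle, skin, spleen, bone,
#'   brain, rest.
#' @param hct hematocrit used when deriving the acidic-phospholipid
#'   association constant from the healthy blood-to-plasma ratio.
#' @return Tissue-to-plasma partition coefficient (dimensionless, > 0).
#' @examples
#' rodgers_rowland_kp(osimertinib_parameters(), "lung")  # ~13, cf. 14.3
#' @export
rodgers_rowland_kp <- function(compound, organ, hct = 0.47) {
  stopifnot(inherits(compound, "compound_parameters"))
  row <- .tissue_composition[.tissue_composition$organ == organ, ]
  if (nrow(row) != 1L) {
    stop("unknown organ '", organ, "'; embedded compositions: ",
         paste(.tissue_composition$organ, collapse = ", "))
  }
  yp <- .base_ionization(compound$pka_base, .ph_plasma)
  yiw <- .base_ionization(compound$pka_base, .ph_iw)
  pvo <- .p_vegoil(compound$logp)

  kpu <- row$f_ew + (yiw / yp) * row$f_iw +
    (pvo * row$f_nl + (0.3 * pvo + 0.7) * row$f_np) / yp

  strong_base <- length(compound$pka_base) >= 1 && compound$pka_base[1] >= 7
  if (strong_base) {
    xiw <- 10^(compound$pka_base[1] - .ph_iw)
    kpu <- kpu + .ka_ap(compound, hct) * (row$ap / 1000) * xiw / yp
  }
  kpu * compound$fup
}

#' Build the partition set for the PBPK model
#'
#' Rodgers-Rowland predictions multiplied by the compound's global
#' \code{kp_scale}, with per-organ overrides taking precedence. The
#' experimental lung coefficient \code{klu_p} (28.5 for osimertinib) is
#' applied as a default lung override when present on the compound.
#'
#' @param compound a \code{compound_parameters} object.
#' @param overrides named numeric vector organ -> Kp, applied verbatim
#'   (no scale factor).
#' @param hct hematocrit for the blood-cell-derived association constant.
#' @return An object of class \code{partition_set}: named list with
#'   \code{kp}, a named vector over the model organs.
#' @examples
#' ps <- build_partition_set(osimertinib_parameters())
#' ps$kp[["lung"]]  # 28.5
#' @export
build_partition_set <- function(compound, overrides = NULL, hct = 0.47) {
  organs <- c("gut", "liver", "lung", "kidney", "adipose", "muscle",
              "skin", "rest")
  kp <- vapply(organs, function(o) {
    rodgers_rowland_kp(compound, o, hct) * compound$kp_scale
  }, numeric(1))
  if (!is.na(compound$klu_p)) kp[["lung"]] <- compound$klu_p
  if (!is.null(overrides)) {
    if (any(overrides <= 0)) stop("partition overrides must be positive")
    bad <- setdiff(names(overrides), organs)
    if (length(bad)) stop("unknown organ(s) in overrides: ",
                          paste(bad, collapse = ", "))
    kp[names(overrides)] <- overrides
  }
  structure(list(kp = kp, kp_scale = compound$kp_scale),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat("<partition_set>\n")
  print(round(x$kp, 3))
  invisible(x)
}
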