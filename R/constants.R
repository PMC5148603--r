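## Physical constants and lookup tables used throughout the package.
## All isotope masses/abundances pinned here in one place (IUPAC values).

## Mass added per H -> D substitution (Da)
HD_MASS_DIFF <- 1.00628

## Proton mass used for m/z conversion (Da)
PROTON_MASS <- 1.00728

## Per-element isotope tables: neutron offset from the lightest isotope,
## exact mass (Da), and natural abundance. Abundances sum to 1 per element.
.ISOTOPES <- list(
  C = data.frame(offset = c(0L, 1L),
                 mass = c(12.0000000, 13.0033548),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(offset = c(0L, 1L),
                 mass = c(1.0078250, 2.0141018),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(offset = c(0L, 1L),
                 mass = c(14.0030740, 15.0001089),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(offset = c(0L, 1L, 2L),
                 mass = c(15.9949146, 16.9991315, 17.9991604),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(offset = c(0L, 1L, 2L, 4L),
                 mass = c(31.9720707, 32.9714585, 33.9678668, 35.9670809),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

.ELEMENTS <- names(.ISOTOPES)

## Average atomic masses (used only for averagine scaling / average MW)
.AVG_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

## Averagine unit: the average elemental composition per residue of a
## "typical" protein, with unit average mass 111.1254 Da.
.AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                     S = 0.0417)
.AVERAGINE_MASS <- 111.1254

## Amino-acid residue compositions (residue = amino acid minus water),
## rows C, H, N, O, S, columns standard one-letter codes.
.RESIDUE_COMPOSITION <- matrix(
  c(## C   H   N   O   S
    3,  5, 1, 1, 0,   # A
    6, 12, 4, 1, 0,   # R
    4,  6, 2, 2, 0,   # N
    4,  5, 1, 3, 0,   # D
    3,  5, 1, 1, 1,   # C
    5,  7, 1, 3, 0,   # E
    5,  8, 2, 2, 0,   # Q
    2,  3, 1, 1, 0,   # G
    6,  7, 3, 1, 0,   # H
    6, 11, 1, 1, 0,   # I
    6, 11, 1, 1, 0,   # L
    6, 12, 2, 1, 0,   # K
    5,  9, 1, 1, 1,   # M
    9,  9, 1, 1, 0,   # F
    5,  7, 1, 1, 0,   # P
    3,  5, 1, 2, 0,   # S
    4,  7, 1, 2, 0,   # T
   11, 10, 2, 1, 0,   # W
    9,  9, 1, 2, 0,   # Y
    5,  9, 1, 1, 0),  # V
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("C", "H", "N", "O", "S"))
)

## Derive a 31-bit child seed from a base seed plus arbitrary key parts
## (strings and numbers). Deterministic across platforms; used so every
## (seed, preset, replicate, time) combination has its own RNG stream.
.deriveSeed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "|"))
             else as.double(p) * 1000
    for (v in codes) h <- (h * 31 + (as.double(v) %% 65536)) %% 2147483647
  }
  as.integer(floor(h))
}
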