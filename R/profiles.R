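# Per-food relative offsets applied to the base gesture parameters.
# Rows follow food ids 01..13; columns are multiplicative offsets (fraction
# of the base value per unit effect size) for the bite period, the eating
# duty-cycle, the pitch and roll gesture amplitudes, the linear-acceleration
# burst and the sensor noise, then *additive* eating-posture offsets in
# radians per unit effect size. The rows form a crossed lattice: pitch
# amplitude on 5 levels crossed with roll amplitude on 3 levels gives every
# food a unique (pitch, roll) cell, while posture, bite period, duty cycle
# and burst cycle through their own level sets at coprime-ish periods, so
# any two foods differ strongly in several channels at once. At effect_size
# 0 every offset vanishes and the foods are kinetically indistinguishable.
# Posture offsets are capped so pitch never folds past +/- pi/2 at the
# default effect size.
.FOOD_OFFSETS <- local({
  pitch5 <- c(-0.35, -0.175, 0, 0.175, 0.35)
  roll3 <- c(-0.35, 0, 0.35)
  post_p3 <- c(-0.3, 0, 0.3)
  post_r4 <- c(-0.3, -0.1, 0.1, 0.3)
  # Period and duty spreads are kept modest so even the fastest eater's
  # movement stays longer than the widest (5 s) analysis window; a full
  # rise-and-return cycle inside one window would cancel its own slopes
  # and erase the food's signature.
  period4 <- c(-0.15, -0.05, 0.05, 0.15)
  durfrac2 <- c(-0.08, 0.08)
  burst5 <- c(-0.3, -0.15, 0, 0.15, 0.3)
  noise2 <- c(-0.1, 0.1)
  k <- 0:12
  m <- cbind(
    period = period4[k %% 4 + 1],
    durfrac = durfrac2[k %% 2 + 1],
    pitch = pitch5[k %% 5 + 1],
    roll = roll3[k %/% 5 + 1],
    burst = burst5[(3 * k) %% 5 + 1],
    noise = noise2[k %% 2 + 1],
    post_pitch = post_p3[k %% 3 + 1],
    post_roll = post_r4[k %% 4 + 1]
  )
  rownames(m) <- sprintf("%02d", 1:13)
  m
})

# Base gesture parameters shared by all foods (the effect_size = 0 gesture).
.BASE_GESTURE <- list(
  bite_period_s = 10,      # one complete eating movement every 10 s
  duty_cycle = 0.62,       # fraction of the cycle spent in the movement
  pitch_amplitude_rad = 0.5,
  roll_amplitude_rad = 0.4,
  linear_accel_burst_mG = 300,
  noise_sd_mG = 50
)

#' Build the gesture profile for one food item
#'
#' Maps a food id to the kinematic parameters of its synthetic eating
#' gesture. All foods share one base gesture; \code{effect_size} scales a
#' fixed per-food offset vector away from it, so the margin between any two
#' foods' parameter vectors grows proportionally with \code{effect_size} and
#' collapses to zero at \code{effect_size = 0} (the null, chance-level
#' configuration). The \code{two_handed} flag comes from the food registry
#' and is independent of \code{effect_size}.
#'
#' @param food_id Food id, \code{"01"}--\code{"13"} (integers accepted).
#' @param effect_size Nonnegative separability dial; default 2 gives
#'   strongly distinguishable gestures, 0 makes all foods identical.
#' @return An object of class \code{gesture_profile}: a list with fields
#'   \code{food_id}, \code{food_item}, \code{bite_period_s},
#'   \code{bite_duration_s}, \code{pitch_amplitude_rad},
#'   \code{roll_amplitude_rad}, \code{linear_accel_burst_mG},
#'   \code{noise_sd_mG}, \code{posture_pitch_rad}, \code{posture_roll_rad},
#'   \code{two_handed} and \code{effect_size}.
#' @examples
#' make_gesture_profile("07", effect_size = 2)
#' @export
make_gesture_profile <- function(food_id, effect_size = 2) {
  stopifnot(is.numeric(effect_size), length(effect_size) == 1,
            is.finite(effect_size), effect_size >= 0)
  id <- if (is.numeric(food_id)) sprintf("%02d", food_id) else as.character(food_id)
  reg <- food_registry()
  if (!id %in% reg$food_id) {
    stop("unknown food_id '", food_id, "'; valid ids are ",
         paste(reg$food_id, collapse = ", "))
  }
  off <- .FOOD_OFFSETS[id, ]
  e <- effect_size
  b <- .BASE_GESTURE
  period <- max(0.5, b$bite_period_s * (1 + e * off[["period"]]))
  duty <- min(0.95, max(0.05, b$duty_cycle * (1 + e * off[["durfrac"]])))
  profile <- list(
    food_id = id,
    food_item = reg$food_item[reg$food_id == id],
    bite_period_s = period,
    bite_duration_s = duty * period,
    pitch_amplitude_rad = max(0, b$pitch_amplitude_rad * (1 + e * off[["pitch"]])),
    roll_amplitude_rad = max(0, b$roll_amplitude_rad * (1 + e * off[["roll"]])),
    linear_accel_burst_mG = max(0, b$linear_accel_burst_mG * (1 + e * off[["burst"]])),
    noise_sd_mG = max(0, b$noise_sd_mG * (1 + e * off[["noise"]])),
    posture_pitch_rad = e * off[["post_pitch"]],
    posture_roll_rad = e * off[["post_roll"]],
    two_handed = reg$two_handed[reg$food_id == id],
    effect_size = e
  )
  structure(profile, class = "gesture_profile")
}

#' @export
print.gesture_profile <- function(x, ...) {
  cat(sprintf("<gesture_profile> %s (%s)%s\n", x$food_id, x$food_item,
              if (x$two_handed) " [two-handed]" else ""))
  cat(sprintf("  bite period %.2f s, duration %.2f s\n",
              x$bite_period_s, x$bite_duration_s))
  cat(sprintf("  pitch amp %.3f rad, roll amp %.3f rad, posture (%.2f, %.2f) rad\n",
              x$pitch_amplitude_rad, x$roll_amplitude_rad,
              x$posture_pitch_rad, x$posture_roll_rad))
  cat(sprintf("  burst %.0f mG, noise sd %.0f mG (effect size %.2f)\n",
              x$linear_accel_burst_mG, x$noise_sd_mG, x$effect_size))
  invisible(x)
}

#' Gesture profiles for a set of foods
#'
#' @param food_ids Food ids; defaults to all thirteen registry items.
#' @param effect_size Separability dial passed to
#'   \code{\link{make_gesture_profile}}.
#' @return Named list of \code{gesture_profile} objects.
#' @export
default_profiles <- function(food_ids = food_registry()$food_id,
                             effect_size = 2) {
  profs <- lapply(food_ids, make_gesture_profile, effect_size = effect_size)
  names(profs) <- vapply(profs, `[[`, "", "food_id")
  profs
}
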