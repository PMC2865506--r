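# pitchsense

Energetics of body pitch during electrosensory prey search.

Weakly electric knifefish hunt at night by swimming with the body pitched
head-down. The posture is hydrodynamically wasteful — measured drag on a body
cast rises from 2.0 mN at level posture to 8.1 mN at 30° (at 15 cm/s) — but
it sweeps a much larger silhouette of the fish's detection volume through
the water, so each metre of travel scans more prey. `pitchsense` puts
numbers on that trade-off for anyone modelling how sensing benefits and
locomotion costs interact: sensory ecologists, biomechanists, and designers
of active-sensing robots.

## The model

The detection volume (*sensorium*) is idealized as a body-fixed cuboid
(H × L × W). At pitch α its projected frontal area is

    A(α) = W (L sin α + H cos α),

maximal at α* = arctan(L/H) with gain √(1 + e²), where e = L/H is the
elongation factor (e ≈ 2.15 for the electrosensory cuboid). Drag follows a
power law in pitch fitted to tow-tank forces, F(α) = a + b αᶜ (α in
degrees), scaled quadratically in speed: F = k(α) v². With swimming power
clamped at P = k v³, the sustainable speed is v = (P/k)^(1/3), the distance
per expected prey encounter is d = 1/(D·A), and the mechanical energy spent
against drag per prey is

    E(α) = P · t = P^(2/3) k(α)^(1/3) / (D · A(α)).

Ribbon-fin thrust is modelled from the surge/heave correlation
F_net = F_surge [cos(α+β) + η sin(α+β)] (η ≈ 0.25, β ≈ 14°), and
counterfactual scenarios clamp either A (a body-fixed, vision-like
sensorium) or k (a movable sensorium the animal could swivel without
pitching its body). A seeded synthetic tow-tank generator supports
end-to-end parameter-recovery validation.

## Worked example

```r
library(pitchsense)

fit <- fit_drag_curve(measured_tow_data())
fit
#> Pitch-dependent drag law (alpha in degrees)
#>   F(alpha) = 0.002 + 0.0002573 * alpha^0.9307  [N] at v_ref = 0.15 m/s
#>   velocity scaling: F ~ v^2
#>   n = 3, RSS = 0 N^2, R^2 = 1.0000

cub <- cuboid_sensorium()     # H = 12.5, L = 26.9, W = 11.6 cm
cfg <- energetics_config()    # P = 0.3 mW, D = 5000 /m^3

reference_thrust_power(fit) * 1e3   # 0.3 mW: 15 cm/s x 2.0 mN
#> [1] 0.3
100 * area_ratio(cub, 30)           # % of neutral-pitch area at 30 deg
#> [1] 194.2025
energy_per_prey(cfg, fit, cub, 0) * 1e6   # microjoules per prey, level
#> [1] 27.58621
optimal_pitch(cfg, fit, cub)              # energy-minimizing pitch (deg)
#> [1] 48.1

# a movable sensorium swivelled to the area-maximizing pitch (~65 deg)
# more than halves the cost per prey:
e0 <- energy_per_prey(cfg, fit, cub, 0)
e0 / energy_per_prey(cfg, fit, cub, area_maximizing_pitch(cub), "clamp_drag")
#> [1] 2.372995

# doubling an active-sensing range costs 16x the emission energy:
active_sensing_energy_cost(80, r_new_m = 0.06, r_old_m = 0.03)  # joules
#> [1] 1280
```

Interpretation: holding 0.3 mW of swimming power, a level-swimming fish
spends ~27.6 μJ against drag per prey encountered; pitching enlarges the
swept area faster than it inflates drag up to ~48°, trimming ~21% off that
cost, and a hypothetical body-independent (movable) sensorium would cut it
by 2.37×. The fourth-power range law shows why extending the sensing range
instead is prohibitively expensive.

`reproduce(load_config())` runs the whole default pipeline and writes the
area, energy, thrust and range-scaling tables plus a `summary.json` of
headline numbers; all constants can be overridden from a YAML config (see
`inst/extdata/example_config.yaml`).

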