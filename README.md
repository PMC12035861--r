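# qresponse

Symbolic quasi-energy response functions for atomic-orbital
density-matrix SCF and coupled-cluster electronic-structure models,
with exact evaluation on a two-level atom.

## What it does, and for whom

Frequency-dependent molecular properties are strength derivatives of
the time-averaged quasi-energy Lagrangian
$\tilde L$, evaluated at zero perturbation strength:

$$\langle\langle A; B_1, \ldots, B_n\rangle\rangle_{\omega_1,\ldots,\omega_n}
= \left.\frac{\partial^{\,n+1}\,\tilde L}
       {\partial\varepsilon_{\omega_A}\,
        \partial\varepsilon_{\omega_{B_1}}\cdots
        \partial\varepsilon_{\omega_{B_n}}}\right|_{\{\varepsilon\}=0}.$$

Deriving these expressions by hand is error-prone past third order.
This package is for developers of response-theory code who want the
*symbolic* part done mechanically: it constructs the model Lagrangian
— density-matrix form $\tilde L^a = \operatorname{Tr}_T[\tilde E^{0,a}
- \tilde S^a\tilde W - \tilde\lambda_a\tilde Y - \tilde\zeta_a\tilde
Z]$ with TDSCF and idempotency constraints, or coupled-cluster form
$\tilde L = \langle e^{\mathrm{ad}_{-T}}(H)\rangle +
\tilde\lambda\cdot(\langle e^{\mathrm{ad}_{-T}}(H)\rangle_\mu -
i\dot{\tilde t}^{\,T})$ with the similarity transform expanded through
4-fold nested commutators — differentiates it with respect to
perturbation multichains, applies the generalized elimination rules
(with $k$ extensive perturbations, wave-function-parameter derivatives
from order $k_{\mathrm{wfn}} \ge \lfloor k/2\rfloor + 1$ and
multipliers from $k_\lambda = \max(k - k_{\mathrm{wfn}} + 1, 0)$; the
2n+1/2n+2 rules are the all-extensive special case), removes what
vanishes at zero strength, and emits the response expression as LaTeX
or a JSON tree, together with response-equation right-hand sides.
Solving those equations numerically is left to the user by design.

For the two-level atom every operator is a 2×2 matrix and the density
derivatives follow a closed frequency-domain recursion, so the package
also evaluates response functions *exactly* (complex rationals, exact
frequency linear forms) and decomposes them into unique terms keyed by
their transition-moment numerators.

## Worked example

Third-order response of the two-level atom through the density-matrix
pipeline, with no elimination (`min_wfn_exten = order` keeps all
density derivatives and removes all multipliers):

```r
library(qresponse)
r <- two_level_response(3)
r$response$expr
#> TrT{V_a^{a}*D^{bc}}

count_unique_terms(r$value)
#> [1] 12

ct <- canonical_terms(r$value)
ct[[1]]$numerator
#> [1] "Va[0,0]" "Vb[0,1]" "Vc[1,0]"
format_scalar(ct[[1]]$coefficient)
#> [1] "-1/(Delta_E - omega_c)/(omega_b + omega_c) + 1/(Delta_E + omega_b)/(omega_b + omega_c)"
```

Reading: after elimination the third-order response reduces to the
time-averaged trace of the once-differentiated field operator against
the second-order density derivative.  Evaluated on the two-level model
with symbolic frequencies, it splits into 12 unique sum-over-states
terms; the one shown couples the diagonal moment of $\hat V_a$ to the
$0\!\to\!1$ transition moments of $\hat V_b$ and $\hat V_c$, with the
familiar frequency-difference denominators ($\Delta E = E_1 - E_0$).
Choosing an admissible elimination instead (`min_wfn_exten = 2`
rewrites the expression through the multiplier ansätze) changes the
symbolic form but — as the tests assert to exact rational equality —
not the value.  The fourth- and fifth-order responses decompose into
54 and 220 unique terms.

A coupled-cluster run is analogous:

```r
b <- perturbation("b", "omega_b", max_diff_order = 1)
c_ <- perturbation("c", freq_sym("omega_b", -1), max_diff_order = 1)
ops <- list(operator_symbol("V_b", deps = list(b = 1), vanishes_at_zero = TRUE),
            operator_symbol("V_c", deps = list(c = 1), vanishes_at_zero = TRUE))
lag <- cc_lagrangian(operator_symbol("H_0"), ops)
res <- cc_response_function(lag, elimination_spec(list(b, c_)))  # L^{bc}
```

With all perturbations extensive and automatic elimination the result
obeys the 2n+1 rule for the amplitudes and the 2n+2 rule for the
multipliers; `cc_response_rhs()` extracts the $\xi$/$\zeta$
right-hand-side vectors with the $(A \mp \omega I)$ left-hand-side
structure attached as metadata.

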