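"""Brute-force dip statistic by direct minimisation over unimodal CDFs.

The dip of an empirical CDF F_n is min over unimodal G of sup|F_n - G|.
A minimising G can be taken piecewise linear with knots at the distinct data
values (plus one knot on each side), with at most one upward jump at the mode.
For every candidate mode position (at a knot, or inside an inter-knot cell)
the problem "minimise eps subject to G within eps of F_n, monotone, convex
left of the mode, concave right of it" is a small linear program.  This
script enumerates all mode positions and solves each LP exactly.

stdin:  JSON {"samples": [[x, ...], ...]}
stdout: JSON [dip, ...]
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def dip_lp(sample):
    x = np.sort(np.asarray(sample, dtype=float))
    n = len(x)
    u, counts = np.unique(x, return_counts=True)
    K = len(u)
    if K == 1:
        return 0.0
    knots = np.concatenate(([u[0] - 1.0], u, [u[-1] + 1.0]))  # t_0..t_{K+1}
    # F level on cell [t_i, t_{i+1}): F_levels[i], i = 0..K
    F_levels = np.concatenate(([0.0], np.cumsum(counts) / n))
    dx = np.diff(knots)  # cell widths, length K+1

    def solve(mode_kind, j, variant=None):
        # variables: eps, g_0..g_{K+1}, [g_jminus if mode at knot j]
        nv = 1 + (K + 2) + (1 if mode_kind == "knot" else 0)
        EPS, G0 = 0, 1
        jm = nv - 1  # index of g_jminus when present

        def gvar(i):
            return G0 + i

        A, b = [], []

        def le(coefs, rhs):  # sum(coefs) <= rhs ; coefs dict var->coef
            row = np.zeros(nv)
            for k, c in coefs.items():
                row[k] += c
            A.append(row)
            b.append(rhs)

        # right-limit variable of cell i (value of G just before t_{i+1})
        def right_of(i):
            if mode_kind == "knot" and i + 1 == j:
                return jm
            return gvar(i + 1)

        # proximity: cells 0..K, then the terminal level 1
        for i in range(K + 1):
            F = F_levels[i]
            for var in (gvar(i), right_of(i)):
                le({var: 1.0, EPS: -1.0}, F)
                le({var: -1.0, EPS: -1.0}, -F)
        le({gvar(K + 1): 1.0, EPS: -1.0}, 1.0)
        le({gvar(K + 1): -1.0, EPS: -1.0}, -1.0)

        # monotone (with the pre-jump value slotted in when mode at a knot)
        chain = [gvar(0)]
        for i in range(1, K + 2):
            if mode_kind == "knot" and i == j:
                chain.append(jm)
            chain.append(gvar(i))
        for a_, b_ in zip(chain[:-1], chain[1:]):
            le({a_: 1.0, b_: -1.0}, 0.0)

        # slope of cell i as a linear form {var: coef}
        def slope(i):
            lo_v = gvar(i)
            hi_v = right_of(i)
            # slope uses start g_i and end right_of(i); for the cell just
            # after a knot-mode, start is g_j (post-jump) -- gvar(i) is right
            return {hi_v: 1.0 / dx[i], lo_v: -1.0 / dx[i]}

        def slope_le(i, k):  # slope(i) <= slope(k)
            row = np.zeros(nv)
            for v_, c in slope(i).items():
                row[v_] += c
            for v_, c in slope(k).items():
                row[v_] -= c
            A.append(row)
            b.append(0.0)

        if mode_kind == "knot":
            left_cells = list(range(0, j))      # cells fully left of mode
            right_cells = list(range(j, K + 1))  # cells fully right
        else:
            left_cells = list(range(0, j))
            right_cells = list(range(j + 1, K + 1))
        for a_, b_ in zip(left_cells[:-1], left_cells[1:]):
            slope_le(a_, b_)   # convex: slopes nondecreasing
        for a_, b_ in zip(right_cells[:-1], right_cells[1:]):
            slope_le(b_, a_)   # concave: slopes nonincreasing
        if mode_kind == "cell" and variant == "A" and j >= 1:
            slope_le(j - 1, j)
        if mode_kind == "cell" and variant == "B" and j <= K - 1:
            slope_le(j + 1, j)

        c = np.zeros(nv)
        c[EPS] = 1.0
        bounds = [(0, None)] + [(0, 1)] * (nv - 1)
        res = linprog(c, A_ub=np.array(A), b_ub=np.array(b), bounds=bounds,
                      method="highs")
        return res.fun if res.status == 0 else np.inf

    best = np.inf
    for j in range(1, K + 1):
        best = min(best, solve("knot", j))
    for j in range(0, K + 1):
        if j == 0:
            # slope left of the first cell is 0, so the convex-junction
            # condition holds automatically: no extra constraint
            best = min(best, solve("cell", j, "A"))
        elif j == K:
            # slope right of the last cell is 0: concave junction automatic
            best = min(best, solve("cell", j, "B"))
        else:
            best = min(best, solve("cell", j, "A"), solve("cell", j, "B"))
    return float(best)


def main():
    payload = json.load(sys.stdin)
    print(json.dumps([dip_lp(s) for s in payload["samples"]]))


if __name__ == "__main__":
    main()
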