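"""Generic convex-minimizer oracle for sparse-group-lasso problems.

Solves an exact smooth reformulation with scipy's SLSQP:

    min f(w) + lambda1 * sum_g q_g * t_g + lambda2 * sum_m c_m * s_m
    s.t. t_g >= ||w_g||_2,  s_m >= |w_m|

where f is either the logistic loss over (X, y) ("fit" mode) or
0.5 * ||w - v||^2 ("prox" mode), q_g are the group penalty weights
(group size to a configurable power) and c_m per-coordinate lasso
weights.  Reads a JSON list of problems on stdin, writes JSON
solutions (w and objective) to stdout.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize

EPS = 1e-18  # smoothing inside the norm constraint only


def solve(prob):
    groups = np.atleast_1d(np.asarray(prob["groups"], dtype=int))  # 1-based group ids
    p = groups.size
    G = groups.max()
    lam1 = float(prob["lambda1"])
    lam2 = float(prob["lambda2"])
    q = np.atleast_1d(np.asarray(prob["q"], dtype=float))          # per-group weights
    c = np.atleast_1d(np.asarray(prob.get("c", np.ones(p)), dtype=float))

    if prob["mode"] == "fit":
        X = np.atleast_2d(np.asarray(prob["X"], dtype=float))
        y = np.atleast_1d(np.asarray(prob["y"], dtype=float))

        def f(w):
            m = y * (X @ w)
            return np.sum(np.logaddexp(0.0, -m))

        def fgrad(w):
            m = y * (X @ w)
            s = 1.0 / (1.0 + np.exp(m))
            return -X.T @ (y * s)
    else:
        v = np.atleast_1d(np.asarray(prob["v"], dtype=float))
        step = float(prob.get("step", 1.0))
        lam1 *= step
        lam2 *= step

        def f(w):
            return 0.5 * np.sum((w - v) ** 2)

        def fgrad(w):
            return w - v

    def obj(z):
        w, t, s = z[:p], z[p:p + G], z[p + G:]
        return f(w) + lam1 * np.sum(q * t) + lam2 * np.sum(c * s)

    def jac(z):
        w = z[:p]
        return np.concatenate([fgrad(w), lam1 * q, lam2 * c])

    cons = []
    for g in range(1, G + 1):
        idx = np.where(groups == g)[0]

        def cfun(z, g=g, idx=idx):
            return z[p + g - 1] - np.sqrt(np.sum(z[idx] ** 2) + EPS)

        def cjac(z, g=g, idx=idx):
            out = np.zeros(z.size)
            nrm = np.sqrt(np.sum(z[idx] ** 2) + EPS)
            out[idx] = -z[idx] / nrm
            out[p + g - 1] = 1.0
            return out

        cons.append({"type": "ineq", "fun": cfun, "jac": cjac})
    for m in range(p):
        for sign in (1.0, -1.0):

            def cfun(z, m=m, sign=sign):
                return z[p + G + m] - sign * z[m]

            def cjac(z, m=m, sign=sign):
                out = np.zeros(z.size)
                out[p + G + m] = 1.0
                out[m] = -sign
                return out

            cons.append({"type": "ineq", "fun": cfun, "jac": cjac})

    z0 = np.zeros(p + G + p)
    if prob["mode"] == "prox":
        z0[:p] = np.atleast_1d(np.asarray(prob["v"], dtype=float)) * 0.5
        z0[p + G:] = np.abs(z0[:p])
        for g in range(1, G + 1):
            idx = np.where(groups == g)[0]
            z0[p + g - 1] = np.sqrt(np.sum(z0[idx] ** 2) + EPS)
    res = minimize(obj, z0, jac=jac, constraints=cons, method="SLSQP",
                   options={"maxiter": 2000, "ftol": 1e-14})
    w = res.x[:p]
    # true (nonsmooth) objective at the solver's w
    gn = np.array([np.linalg.norm(w[groups == g]) for g in range(1, G + 1)])
    true_obj = f(w) + lam1 * np.sum(q * gn) + lam2 * np.sum(c * np.abs(w))
    return {"w": w.tolist(), "objective": float(true_obj),
            "success": bool(res.success)}


def main():
    problems = json.load(sys.stdin)
    json.dump([solve(pr) for pr in problems], sys.stdout)


if __name__ == "__main__":
    main()
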