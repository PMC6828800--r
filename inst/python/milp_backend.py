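"""Batch backend for binary minimum-set covering programs.

Reads a JSON file with a list of problems, solves each as a 0/1 integer
linear program with HiGHS (scipy.optimize.milp), and writes a JSON list of
results. One process solves the whole batch so interpreter start-up is paid
once per batch, not once per solve.

Problem fields:
  n        -- number of binary variables (planning units)
  weights  -- objective coefficients, length n
  ai,aj,ax -- triplets (0-based) of the constraint matrix A (species x units)
  m        -- number of constraint rows
  rhs      -- right-hand sides, length m (constraints are A x >= rhs)
  gap      -- relative MIP optimality gap
Result fields:
  status   -- "optimal" | "infeasible" | "error"
  selected -- 0-based indices of selected units
  objective, mip_gap, message
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, milp


def solve_one(p):
    n = int(p["n"])
    # length-1 arrays arrive JSON-unboxed as scalars
    w = np.atleast_1d(np.asarray(p["weights"], dtype=float))
    m = int(p["m"])
    gap = float(p.get("gap", 0.0))
    ai = np.atleast_1d(np.asarray(p["ai"], dtype=int))
    aj = np.atleast_1d(np.asarray(p["aj"], dtype=int))
    ax = np.atleast_1d(np.asarray(p["ax"], dtype=float))
    rhs = np.atleast_1d(np.asarray(p["rhs"], dtype=float))
    constraints = []
    if m > 0 and ai.size > 0:
        A = sparse.csc_matrix((ax, (ai, aj)), shape=(m, n))
        constraints = [LinearConstraint(A, rhs, np.full(m, np.inf))]
    elif m > 0:
        # no nonzero coefficients: feasible iff every rhs <= 0
        if np.any(rhs > 0):
            return {"status": "infeasible", "selected": [],
                    "objective": None, "mip_gap": None, "message": ""}
        constraints = []
    options = {"presolve": True}
    if gap > 0:
        options["mip_rel_gap"] = gap
    if "time_limit" in p:
        options["time_limit"] = float(p["time_limit"])
    res = milp(c=w, constraints=constraints,
               integrality=np.ones(n), bounds=(0, 1), options=options)
    if res.status == 2:
        return {"status": "infeasible", "selected": [],
                "objective": None, "mip_gap": None,
                "message": str(res.message)}
    if res.x is None:
        return {"status": "error", "selected": [], "objective": None,
                "mip_gap": None, "message": str(res.message)}
    sel = np.nonzero(res.x > 0.5)[0]
    # status 1 = resource limit with incumbent: feasible, gap as reported
    return {"status": "optimal" if res.status == 0 else "limit",
            "selected": [int(i) for i in sel],
            "objective": float(res.fun),
            "mip_gap": float(res.mip_gap) if res.mip_gap is not None else None,
            "message": str(res.message)}


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    results = []
    for p in payload["problems"]:
        try:
            results.append(solve_one(p))
        except Exception as exc:  # surfaced as a solver error in R
            results.append({"status": "error", "selected": [],
                            "objective": None, "mip_gap": None,
                            "message": repr(exc)})
    with open(argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv)
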