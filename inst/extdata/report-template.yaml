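colours:
  low: green
  medium: orange
  high: red
  unknown: grey
unknown_text: >-
  We could not score this domain because some answers were missing. Please
  complete these questions at your next survey so your profile stays accurate.
recommendations:
  alcohol:
    medium: >-
      Aim to drink less than two standard drinks on any day, and keep your
      weekly total at or below current low-risk guidelines.
    high: >-
      Reduce your drinking to no more than 14 standard drinks per week and
      less than two standard drinks per day; talk with your doctor about
      support for cutting down.
  bmi:
    medium: >-
      Work toward a body-mass index in the healthy 18-25 range through a
      balanced diet and regular physical activity.
    high: >-
      A body-mass index of 30 or over raises dementia and cardiometabolic
      risk; discuss a sustainable weight-management plan with your doctor.
  hypertension:
    medium: >-
      Keep up your regular blood-pressure check-ups and work with your doctor
      toward full medical management.
    high: >-
      Arrange a blood-pressure check with your doctor and ensure any diagnosis
      is medically managed.
  cholesterol:
    medium: >-
      Keep up regular cholesterol checks and continue working toward managing
      your levels with your doctor.
    high: >-
      Arrange a cholesterol check with your doctor and ensure any diagnosis is
      medically managed.
  diabetes:
    medium: >-
      Keep up regular blood-sugar checks and continue working toward managing
      your levels with your doctor.
    high: >-
      Arrange a blood-sugar check with your doctor and ensure any diabetes
      diagnosis is medically managed.
  smoking:
    medium: >-
      Even occasional smoking adds risk; aim to stop completely and ask your
      doctor about quit support.
    high: >-
      Not smoking is one of the most effective ways to lower your risk; ask
      your doctor or a quit line about support to stop.
  cognitive_activity:
    high: >-
      Engage in socially and cognitively stimulating activities -- reading,
      puzzles, courses, clubs, music -- several times a month or more.
  physical_activity:
    high: >-
      Build up to at least 150 minutes of moderate physical activity per week
      (about 600 MET-minutes), such as brisk walking.
  diet:
    medium: >-
      Move further toward a Mediterranean-style eating pattern: more leafy
      greens, vegetables, berries, nuts, wholegrains, fish and olive oil.
    high: >-
      Adopt a Mediterranean-style eating pattern: more leafy greens,
      vegetables, berries, nuts, wholegrains, fish and olive oil, and fewer
      fried and processed foods.
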