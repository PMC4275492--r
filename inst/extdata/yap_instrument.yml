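# Bundled 15-item segmented-day activity instrument (YAP-style).
# Prompts are placeholders, not the published item wording.
scale_min: 1
scale_max: 5
sections:
  - activity_school
  - activity_out_of_school
  - sedentary
items:
  - item_id: q01_transport_to_school
    section: activity_school
    window_type: transport_to_school
    prompt: "How active were you while travelling to school last week?"
  - item_id: q02_physical_education
    section: activity_school
    window_type: physical_education
    prompt: "How active were you during PE class last week?"
  - item_id: q03_recess
    section: activity_school
    window_type: recess
    prompt: "How active were you at recess last week?"
  - item_id: q04_lunch
    section: activity_school
    window_type: lunch
    prompt: "How active were you during lunch time last week?"
  - item_id: q05_transport_from_school
    section: activity_school
    window_type: transport_from_school
    prompt: "How active were you while travelling home from school last week?"
  - item_id: q06_after_school
    section: activity_out_of_school
    window_type: after_school
    prompt: "How active were you after school (before dinner) last week?"
  - item_id: q07_before_school
    section: activity_out_of_school
    window_type: before_school
    prompt: "How active were you before school last week?"
  - item_id: q08_evening
    section: activity_out_of_school
    window_type: evening
    prompt: "How active were you in the evening last week?"
  - item_id: q09_saturday
    section: activity_out_of_school
    window_type: saturday
    prompt: "How active were you last Saturday?"
  - item_id: q10_sunday
    section: activity_out_of_school
    window_type: sunday
    prompt: "How active were you last Sunday?"
  - item_id: q11_tv
    section: sedentary
    prompt: "How much time did you spend watching TV last week?"
  - item_id: q12_video_games
    section: sedentary
    prompt: "How much time did you spend playing video games last week?"
  - item_id: q13_computer
    section: sedentary
    prompt: "How much time did you spend using a computer or phone last week?"
  - item_id: q14_sitting_weekday
    section: sedentary
    prompt: "How much of your free time on school days did you spend sitting?"
  - item_id: q15_sitting_weekend
    section: sedentary
    prompt: "How much of your weekend did you spend sitting?"
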